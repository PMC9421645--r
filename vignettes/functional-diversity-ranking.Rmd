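---
title: "Functional-diversity ranking of fragment screens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-diversity ranking of fragment screens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragrank)
```

## The problem

Crystallographic fragment screens test hundreds of small, weakly binding
molecules against a protein and solve the structures of the complexes that
form. The conventional way to assemble such a library is to maximize
*structural* diversity of the molecules (e.g. MACCS fingerprints with a
MaxMin picker). fragrank implements and evaluates an alternative: treat a
fragment as *what it does* — the set of protein-ligand interactions it has
been observed to form across targets — and select fragments that maximize
*functional* diversity, so that a screen of a given size explores as many
distinct interactions as possible.

## Functional activity and interaction fingerprints

For every protein-fragment complex the package computes a binary
interaction fingerprint (IFP) with up to eight interaction types per
protein site:

| type | rule (heavy-atom geometry) | default cutoff |
|---|---|---|
| `hydrophobic` | hydrophobic C/S (and Cl/Br/I) pairs | d <= 4.0 A |
| `hbond_donor` | protein donor to ligand acceptor | d <= 3.5 A |
| `hbond_acceptor` | protein acceptor to ligand donor | d <= 3.5 A |
| `salt_positive` | protein cation to ligand anion | d <= 4.0 A |
| `salt_negative` | protein anion to ligand cation | d <= 4.0 A |
| `metal` | protein-side metal to ligand acceptor/anion | d <= 3.0 A |
| `aromatic_f2f` | ring centroids, interplanar angle <= 30 deg | d <= 5.0 A |
| `aromatic_e2f` | ring centroids, angle in 60-120 deg | d <= 5.0 A |

The *residue IFP* sets bit (r, t) when any atom of residue r makes a
type-t contact; the *atomic IFP* resolves the individual protein atom
(aromatic contacts mark every ring atom, so the residue bit is always the
OR of the corresponding atomic bits). Each set bit becomes an
*interaction key* `target|site|type`, and a fragment's **functional
profile** is the union of its keys over all complexes it appears in,
including multiple bound copies in one crystal.

Geometric criteria in this family of tools differ in detail between
implementations; the defaults above follow common interaction-fingerprint
practice and are deliberately isolated in `geometry_params()` (and YAML
configs) so they can be matched to any reference setting. Two numerical
choices matter:

* **Detection is hydrogen-free.** Fragment-screen models rarely carry
  hydrogens, so hydrogen bonds and salt bridges are donor/acceptor
  heavy-atom distances, and donor-angle feasibility is not evaluated.
  This over-calls borderline contacts relative to an H-aware engine.
* **Atom typing.** Protein atoms are typed by residue template (Lys NZ
  positive donor, Asp OD1/OD2 negative acceptors, backbone N/O, ring
  membership for His/Phe/Tyr/Trp); metals are their own class and are
  excluded from the hydrogen-bond and salt-bridge rules. Ligand atoms are
  typed from distance-inferred connectivity: carboxylate-like terminal
  oxygens become anions, short (<= 1.25 A) terminal C-N bonds are read as
  nitriles (acceptor) while longer ones are amine-like (donor, cationic
  unless amide-adjacent), ring nitrogens accept, and quaternary nitrogens
  are cations without donor capacity. A single-neighbour oxygen is
  ambiguous without hydrogens and is treated as both donor and acceptor.

Crystallographic hygiene: waters and common buffer/cryoprotectant residues
are dropped; for alternate locations the highest-occupancy conformer is
kept (ties to altloc A); non-water HETATM groups such as metal cofactors
stay on the protein side. Residues are identified by
`chain:resname:number[insertion]`, assuming consistent numbering across
crystals of one target; no structural alignment is attempted, and
symmetry mates are out of scope.

## Greedy functional-diversity ranking

Given profiles restricted to a target set, the ranking appends fragments
one at a time, always taking the fragment that contributes the most *novel*
interaction keys (greedy maximum coverage). Because many fragments tie,
the candidate list is shuffled before each run (run r uses seed
`seed + r - 1`) and ties go to the earliest shuffled candidate; repeated
runs (100 by default) yield a mean +/- sd **recovery curve**: the fraction
of the interaction universe covered at each library size. The **minimum
cover size** reported is the greedy cover — the protocol's own number, not
the NP-hard optimum — but the classic guarantee applies: greedy coverage
at every size k is at least (1 - 1/e) of the optimal size-k coverage,
which the test suite verifies against brute-force enumeration on small
instances. Fragments whose remaining gain is zero are still ranked (they
keep their shuffled order at the tail) so that statistics at fixed library
sizes are well defined.

A canonical run then partitions the library into the groups used for
property profiling: the top-100 most informative fragments, the remaining
members of the minimum cover, other bound fragments, redundant binders
(bound, but contributing no novel key when selected), and never-bound
fragments. Group membership is taken from a single canonical run (the
first run of the master seed) rather than aggregated across runs; with
ties broken by shuffle, membership near the boundary can vary between
runs, and a single-run definition keeps every downstream table exactly
reproducible from one seed.

## Baselines and evaluation

* **Random**: seeded uniform shuffles of the same rankable pool.
* **Structurally diverse**: MACCS keys (OpenBabel via ChemmineOB) with a
  MaxMin picker; the initial pick is uniform-random per run, later picks
  maximize the minimum Tanimoto distance to the selection. The full
  ordering is returned so every prefix is the size-k diverse set.
* **Pair analysis**: for every pair of bound fragments sharing a bound
  target, molecular similarity (ECFP2, i.e. circular radius 1) is compared
  with functional similarity (Tanimoto over IFP keys — the similarity
  metric for fingerprints is a package choice, as is using all unordered
  pairs of *bound* fragments as the denominator for summary fractions;
  both are configurable).

**Leave-one-out evaluation** holds out one target, ranks fragments using
only the remaining targets' profiles, and measures recovery of the
held-out target's keys. Only fragments informative on the training targets
can be ranked; past that pool, zero-information "dummy fragments" pad the
curves to `max_size` (default 200). Improvement statistics are the
relative change of mean recoveries at a given size (ratio of means rather
than mean of per-run ratios, which avoids instability when single runs
recover nothing). The **impact matrix** entry (i, j) is the percentage
change in mean recovery of held-out target j at size k when training
target i is included versus excluded; an absolute-difference variant is
available but off by default, matching the relative phrasing used for
such scores.

## The synthetic-data module

Because real screen deposits are external, all tests run on synthetic
data from two generators.

**Abstract screens** (`generate_binding_matrix()`) draw a tested-on
matrix, binding events and interaction keys with a controllable
redundancy dial. Defaults emulate a ten-target screen of a ~500-fragment
library: `tested_rate = 0.85` (most fragments screened on most targets,
as under a tested-on->=7-of-10 inclusion rule), `bind_rate = 0.064` (a
per-pair crystallographic hit rate of ~6%, which makes ~43% of fragments
bind at least one target in the default configuration — the realistic
binder fraction for such screens), negative-binomial profile sizes (mean
5, dispersion 3), `keys_per_target = 120`, `redundancy = 2.5` and
`cross_target_signal = 0.3`. Each fragment owns a latent slot repertoire
drawn from a shared pool whose size is calibrated numerically so the
realized carriers-per-key matches the `redundancy` dial (uniform draws
leave some slots unused, which would otherwise inflate the realized
redundancy); a binder becomes informative on each other tested target
with probability `cross_target_signal`, expressing the same repertoire
there — the planted, transferable cross-target signal that leave-one-out
evaluation measures. With `redundancy = 1` the generator switches to
disjoint-key construction (every key has exactly one carrier, no
cross-target signal), the natural null model. What the abstract generator
does *not* emulate: correlated binding between chemically similar
fragments, target-specific hit-rate variation, and any geometry — so
passing ranking/evaluation tests demonstrates correctness of the
selection machinery, not of structure interpretation.

**Planted miniature complexes** (`generate_complex_fixture()`) build PDB
text in which each requested interaction type is planted as an isolated
probe pair (stations 30 A apart, decoy atoms beyond 8 A), with at least
0.3 A / 10 deg of margin inside every geometric boundary, followed by a
seeded random rigid motion. Probe chemistry is chosen so no second rule
can fire within the margins: an arginine probe with unmodelled NH1/NH2
(the charged CZ is not a donor) plants the protein-positive salt bridge, a
quaternary ammonium ligand (cationic, no N-H) the protein-negative one,
and histidine x 1,3,5-triazine rings (whose carbons are all
nitrogen-bonded, hence not hydrophobic) the two aromatic geometries —
e.g. a Lys-NZ/carboxylate pair could not keep simultaneous margins from
the 3.5 A hydrogen-bond and 4.0 A salt-bridge cutoffs. The generator
cross-checks all planted coordinates with its own flags and errors on any
unintended contact ("unplantable spec"), so fixtures are verified by
construction, independently of the detection engine under test. These
fixtures are synthetic probe systems: the ligand groups are disconnected
functional-group probes sharing one residue, not a chemically sensible
molecule, and the "protein" is a set of isolated residues.

Synthetic fragment SMILES come from a combinatorial scaffold x
substituent catalogue generated in code (132 valid structures, recycled);
they stand in for a real catalogue wherever molecular fingerprints or
descriptors are needed.

## Problem sizes and reproducibility

The test suite exercises: exhaustive greedy-step optimality on 200 random
instances of up to 15 fragments; brute-force max-coverage comparisons on
50 instances of up to 12 fragments; 100 randomized planted complexes for
the residue/atomic consistency property; and leave-one-out comparisons on
a 200-fragment, 5-target planted-redundancy screen with 100 runs per
configuration — sizes at which every oracle is exact and the full suite
runs in about a minute. All randomness flows from explicit master seeds
(run r of a protocol uses `seed + r - 1`), and rerunning any command-line
pipeline with an identical configuration reproduces byte-identical CSVs.

On that 200-fragment screen, roughly a quarter of fragments bind at least
one target, so the rankable pool in a leave-one-out split is ~50
fragments and both functional and random mean curves reach the same
ceiling near library size 50; comparisons of the two methods are
informative below that saturation point, where the functional ranking
recovers substantially more of the unseen target's interactions, and the
two curves tie above it. With the redundancy dial at 1 and no
cross-target signal the two methods are statistically indistinguishable,
as they should be: there is nothing transferable to exploit.

## Known limitations

* The greedy cover is a protocol definition, not a set-cover optimum.
* Hydrogen-free detection cannot distinguish donor/acceptor roles of
  hydroxyls or the protonation of histidine; typing errs toward
  permissiveness.
* Cross-crystal residue identity relies on consistent author numbering
  per target.
* Interactions with symmetry mates, halogen bonds, cation-pi and
  water-mediated bridges are outside the eight-type scheme.
* ECFP2/MACCS fingerprints come from OpenBabel; other toolkits' variants
  of the same fingerprints differ in minor details, which matters only
  for exact bit-level comparisons, not for the rank orderings used here.
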