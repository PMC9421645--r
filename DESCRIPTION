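Package: fragrank
Title: Functional-Diversity Ranking of Crystallographic Fragment Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes residue-level and atomic-level protein-ligand
    interaction fingerprints (IFPs) from fragment-screen crystal structures,
    ranks fragments greedily by the novel interactions they contribute to a
    growing library, and evaluates functionally diverse fragment selections
    against random and structurally diverse (MACCS + MaxMin) baselines.
    Includes leave-one-out unseen-target information-recovery curves,
    pairwise target impact scores, fragment property profiling, and a
    synthetic-data module that generates abstract fragment-target-interaction
    screens with tunable functional redundancy as well as miniature PDB
    complexes with geometrically planted interactions of all eight supported
    types.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
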