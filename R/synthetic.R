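## Synthetic-data generators. Two flavours:
##   * abstract fragment x target x interaction incidence data with a
##     tunable functional-redundancy dial, feeding the ranking and
##     evaluation machinery without any structures;
##   * miniature PDB complexes with geometrically planted interactions of
##     each of the eight types, feeding the parsing/typing/detection
##     pipeline. All fixtures are synthetic probe systems, not real
##     proteins.

#' Specification for an abstract synthetic screen
#'
#' Defaults emulate a ten-target crystallographic fragment screen of a
#' ~500-fragment library in which most fragments are screened on most
#' targets, roughly 40-45% of fragments bind at least one target, binders
#' hit one to a few targets, and several fragments carry each interaction
#' key (functional redundancy).
#'
#' @param n_fragments library size.
#' @param n_targets number of protein targets.
#' @param keys_per_target maximum interaction-key universe per target.
#' @param profile_size_mean,profile_size_dispersion mean and negative
#'   binomial dispersion of keys per bound fragment-target pair.
#' @param redundancy expected number of fragments carrying each realized
#'   key (>= 1). `redundancy = 1` switches to disjoint-key construction:
#'   every key has exactly one carrier.
#' @param bind_rate probability a tested fragment binds a target.
#' @param tested_rate fraction of fragment x target pairs screened.
#' @param cross_target_signal probability that a fragment informative on
#'   one target re-uses its latent interaction repertoire on another bound
#'   target (drives unseen-target transfer; ignored when `redundancy = 1`).
#' @param seed generation seed.
#' @return A `"synthetic_spec"` list.
#' @export
synthetic_spec <- function(n_fragments = 520L, n_targets = 10L,
                           keys_per_target = 120L,
                           profile_size_mean = 5, profile_size_dispersion = 3,
                           redundancy = 2.5, bind_rate = 0.064,
                           tested_rate = 0.85, cross_target_signal = 0.3,
                           seed = 0L) {
  s <- list(n_fragments = as.integer(n_fragments),
            n_targets = as.integer(n_targets),
            keys_per_target = as.integer(keys_per_target),
            profile_size_mean = profile_size_mean,
            profile_size_dispersion = profile_size_dispersion,
            redundancy = redundancy, bind_rate = bind_rate,
            tested_rate = tested_rate,
            cross_target_signal = cross_target_signal,
            seed = as.integer(seed))
  stopifnot(s$n_fragments >= 1, s$n_targets >= 1, s$keys_per_target >= 1,
            s$profile_size_mean >= 1, s$redundancy >= 1,
            s$bind_rate >= 0, s$bind_rate <= 1,
            s$tested_rate >= 0, s$tested_rate <= 1,
            s$cross_target_signal >= 0, s$cross_target_signal <= 1)
  structure(s, class = "synthetic_spec")
}

## active slot-pool size so that the expected carriers-per-USED-key equals
## the requested redundancy (uniform draws leave some keys unused, which
## inflates the mean among used keys; invert numerically)
calibrate_pool <- function(total_draws, redundancy, max_m, cap) {
  lo <- max(max_m, 2)
  if (lo >= cap) return(cap)
  carriers <- function(P) {
    lam <- total_draws / P
    lam / (1 - exp(-lam))
  }
  if (carriers(cap) >= redundancy) return(cap)
  if (carriers(lo) <= redundancy) return(lo)
  as.integer(round(stats::uniroot(function(P) carriers(P) - redundancy,
                                  c(lo, cap))$root))
}

#' Generate an abstract synthetic screen dataset
#'
#' Draws a tested-on matrix, binding events, and per-bound-pair interaction
#' keys according to the spec, and returns both the dataset and the ground
#' truth used to plant it. With `redundancy > 1`, keys are drawn from a
#' shared slot pool sized so the realized carriers-per-key matches the
#' redundancy dial; each fragment owns a latent repertoire that it re-uses
#' across its targets with probability `cross_target_signal`, planting the
#' cross-target transfer that leave-one-out evaluation measures. With
#' `redundancy = 1`, every assignment allocates fresh keys, so every key
#' has exactly one carrier and no cross-target signal exists.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `dataset` (a `"screen_dataset"` with synthetic SMILES)
#'   and `ground_truth` (`carriers`: key -> fragment ids; `informativeness`:
#'   unique keys per fragment; `mean_redundancy`: realized carriers per
#'   key).
#' @export
generate_binding_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  fid <- sprintf("F%04d", seq_len(spec$n_fragments))
  tid <- sprintf("T%02d", seq_len(spec$n_targets))
  tested <- matrix(stats::runif(spec$n_fragments * spec$n_targets) <
                     spec$tested_rate,
                   spec$n_fragments, spec$n_targets,
                   dimnames = list(fid, tid))
  ## base binding events, independent per tested pair
  bound <- tested & matrix(stats::runif(length(tested)) < spec$bind_rate,
                           nrow(tested))

  m_draw <- function(n) {
    if (n == 0) return(integer(0))
    1L + stats::rnbinom(n, mu = spec$profile_size_mean - 1,
                        size = spec$profile_size_dispersion)
  }

  profiles <- stats::setNames(vector("list", spec$n_fragments), fid)
  types <- names(interaction_types())
  key_of <- function(t, slots)
    sprintf("%s|s%03d|%s", t, slots, types[(slots %% 8L) + 1L])

  if (spec$redundancy > 1) {
    ## cross-target signal: a fragment informative somewhere becomes
    ## informative on each other tested target with this probability,
    ## re-using its latent slot repertoire there (the transferable part of
    ## its functional activity). Base bindings draw fresh slots.
    induced <- matrix(FALSE, spec$n_fragments, spec$n_targets,
                      dimnames = dimnames(tested))
    binder <- rowSums(bound) > 0
    for (i in which(binder)) for (j in seq_len(spec$n_targets)) {
      if (tested[i, j] && !bound[i, j] &&
          stats::runif(1) < spec$cross_target_signal)
        induced[i, j] <- TRUE
    }
    bound <- bound | induced
    pairs <- which(bound, arr.ind = TRUE)
    ## each fragment owns one latent slot repertoire (its transferable
    ## functional identity, sized by the profile-size distribution) and
    ## expresses it on every target it binds
    m_frag <- m_draw(spec$n_fragments)
    if (max(m_frag) > spec$keys_per_target)
      stop("infeasible spec: keys_per_target (", spec$keys_per_target,
           ") smaller than a drawn profile size (", max(m_frag), ")")
    draws_per_target <- if (nrow(pairs))
      sum(m_frag[pairs[, 1]]) / spec$n_targets else 0
    P <- calibrate_pool(draws_per_target, spec$redundancy, max(m_frag),
                        spec$keys_per_target)
    latent <- lapply(seq_len(spec$n_fragments), function(i)
      sample.int(P, min(m_frag[i], P)))
    if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; t <- tid[pairs[k, 2]]
      profiles[[i]] <- c(profiles[[i]], key_of(t, latent[[i]]))
    }
  } else {
    pairs <- which(bound, arr.ind = TRUE)
    m_pair <- m_draw(nrow(pairs))
    if (length(m_pair) && max(m_pair) > spec$keys_per_target)
      stop("infeasible spec: keys_per_target (", spec$keys_per_target,
           ") smaller than a drawn profile size (", max(m_pair), ")")
    if (spec$cross_target_signal > 0)
      warning("redundancy = 1 forces disjoint keys; ",
              "cross_target_signal ignored")
    next_slot <- stats::setNames(rep(1L, spec$n_targets), tid)
    if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; t <- tid[pairs[k, 2]]; m <- m_pair[k]
      if (next_slot[t] + m - 1L > spec$keys_per_target)
        stop("infeasible spec: keys_per_target too small for disjoint ",
             "(redundancy = 1) construction")
      slots <- next_slot[t]:(next_slot[t] + m - 1L)
      next_slot[t] <- next_slot[t] + m
      profiles[[i]] <- c(profiles[[i]], key_of(t, slots))
    }
  }
  profiles <- lapply(profiles, function(x)
    sort(unique(if (is.null(x)) character(0) else x)))

  fragments <- data.frame(fragment_id = fid,
                          smiles = synthetic_smiles(spec$n_fragments),
                          stringsAsFactors = FALSE)
  dataset <- screen_dataset(fragments, tid, tested, profiles, profiles,
                            min_tested = 0L)
  all_keys <- unlist(profiles, use.names = FALSE)
  carrier_n <- table(all_keys)
  carriers <- lapply(stats::setNames(names(carrier_n), names(carrier_n)),
                     function(k) fid[vapply(profiles, function(p)
                       k %in% p, logical(1))])
  list(dataset = dataset,
       ground_truth = list(
         carriers = carriers,
         informativeness = vapply(profiles, length, integer(1)),
         mean_redundancy = if (length(carrier_n)) mean(carrier_n) else 0))
}

#' Synthetic fragment-like SMILES catalogue
#'
#' Combinatorial scaffold x substituent SMILES strings (all valid by
#' construction), recycled when more than the catalogue size is requested.
#' Purely synthetic stand-ins for a real fragment catalogue.
#'
#' @param n number of SMILES to return.
#' @return Character vector of length `n`.
#' @export
synthetic_smiles <- function(n) {
  cores <- c("c1ccccc1", "c1ccncc1", "c1cncnc1", "c1ccoc1", "c1ccsc1",
             "c1cc[nH]c1", "C1CCCCC1", "C1CCNCC1", "C1CCOCC1", "C1CCCC1",
             "c1cc[nH]n1", "C1CCNC1")
  subs <- c("", "C", "CC", "O", "OC", "N", "NC(=O)", "CC(=O)", "Cl", "F",
            "OC(=O)")
  grid <- expand.grid(s = subs, c = cores, stringsAsFactors = FALSE)
  cat_smiles <- paste0(grid$s, grid$c)
  rep_len(cat_smiles, n)
}

## ---- planted miniature complexes -----------------------------------------

#' Specification for a planted miniature complex
#'
#' Each plant is one protein-side probe group and one ligand-side probe
#' group positioned so that exactly one interaction of the requested type
#' is formed, with at least 0.3 Angstrom / 10 degrees of margin inside
#' every geometric boundary. Default distances/angles sit comfortably
#' inside the [geometry_params()] defaults. Decoy atoms (carbons more than
#' 8 Angstrom from everything) are silent by construction.
#'
#' @param types character vector of interaction type names (see
#'   [interaction_types()]), or `"all"` for one plant of each type.
#' @param distances optional numeric vector (same length) of planted
#'   distances: atom-atom for the pair rules, centroid-centroid for the
#'   aromatic ones.
#' @param angles optional numeric vector of interplanar angles (aromatic
#'   types only; ignored elsewhere).
#' @param decoy_atoms number of protein-side decoy carbons.
#' @return A `"planted_complex_spec"`.
#' @export
planted_complex_spec <- function(types = "all", distances = NULL,
                                 angles = NULL, decoy_atoms = 6L) {
  if (identical(types, "all")) types <- names(interaction_types())
  stopifnot(all(types %in% names(interaction_types())))
  def_d <- c(hydrophobic = 3.5, aromatic_f2f = 4.3, aromatic_e2f = 4.6,
             hbond_donor = 2.9, hbond_acceptor = 2.9, salt_positive = 3.6,
             salt_negative = 3.6, metal = 2.5)
  def_a <- c(hydrophobic = NA, aromatic_f2f = 0, aromatic_e2f = 90,
             hbond_donor = NA, hbond_acceptor = NA, salt_positive = NA,
             salt_negative = NA, metal = NA)
  if (is.null(distances)) distances <- unname(def_d[types])
  if (is.null(angles)) angles <- unname(def_a[types])
  stopifnot(length(distances) == length(types),
            length(angles) == length(types))
  structure(list(types = types, distances = distances, angles = angles,
                 decoy_atoms = as.integer(decoy_atoms)),
            class = "planted_complex_spec")
}

## station builders: local frames with the protein probe anchored at the
## origin and the ligand group along +x. Each atom row carries the
## generator's own typing flags (hp, don, acc, chg, met, arom) used for the
## unplanted-contact self-check; the package's typing machinery never sees
## them.
station_atom <- function(side, resname, name, element, x, y, z,
                         hp = FALSE, don = FALSE, acc = FALSE, chg = "0",
                         met = FALSE, arom = FALSE) {
  data.frame(side = side, resname = resname, name = name, element = element,
             x = x, y = y, z = z, hp = hp, don = don, acc = acc, chg = chg,
             met = met, arom = arom, stringsAsFactors = FALSE)
}

## pentagon/hexagon vertices: centroid ctr, unit normal nrm, radius r
ring_vertices <- function(ctr, nrm, r, n, phase = 90) {
  nrm <- unit(nrm)
  ref <- if (abs(nrm[2]) < 0.9) c(0, 1, 0) else c(0, 0, 1)
  u <- unit(ref - sum(ref * nrm) * nrm)
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  th <- (phase + (360 / n) * (seq_len(n) - 1)) * pi / 180
  t(vapply(th, function(a) ctr + r * (cos(a) * u + sin(a) * v),
           numeric(3)))
}

build_station <- function(type, d, ang) {
  P <- function(...) station_atom("protein", ...)
  L <- function(...) station_atom("ligand", "LIG", ...)
  switch(type,
    hydrophobic = list(atoms = rbind(
      P("LEU", "CB",  "C", -2.6, 0, 1.0, hp = TRUE),
      P("LEU", "CG",  "C", -1.3, 0, 0.8, hp = TRUE),
      P("LEU", "CD1", "C",  0.0, 0, 0.0, hp = TRUE),
      P("LEU", "CD2", "C", -1.3, 0, 2.2, hp = TRUE),
      L("C1", "C", d, 0, 0, hp = TRUE),
      L("C2", "C", d + 1.52, 0, 0, hp = TRUE))),
    hbond_donor = list(atoms = rbind(
      P("GLY", "N",  "N",  0.0, 0, 0.0, don = TRUE),
      P("GLY", "CA", "C", -1.47, 0, 0.0),
      P("GLY", "C",  "C", -2.2, 0, 1.2),
      P("GLY", "O",  "O", -1.7, 0, 2.35, acc = TRUE),
      L("O1", "O", d, 0, 0, acc = TRUE, don = TRUE),
      L("C1", "C", d + 0.86, 0.91, 0),
      L("C2", "C", d + 2.37, 0.91, 0, hp = TRUE))),
    hbond_acceptor = list(atoms = rbind(
      P("GLY", "O",  "O",  0.0, 0, 0.0, acc = TRUE),
      P("GLY", "C",  "C", -1.23, 0, 0.0),
      P("GLY", "CA", "C", -2.0, 0, 1.1),
      P("GLY", "N",  "N", -3.2, 0, 1.3, don = TRUE),
      L("N1", "N", d, 0, 0, don = TRUE, chg = "+"),
      L("C1", "C", d + 1.47, 0, 0),
      L("C2", "C", d + 2.04, 1.39, 0, hp = TRUE))),
    salt_positive = list(atoms = rbind(
      ## Arg probe with disordered NH1/NH2 (absent, as often unmodelled):
      ## the charged guanidinium carbon is not an H-bond donor, so only the
      ## salt-bridge rule can fire at the planted distance
      P("ARG", "CD", "C", -2.3, 0, 1.0),
      P("ARG", "NE", "N", -1.33, 0, 0.0, don = TRUE),
      P("ARG", "CZ", "C",  0.0, 0, 0.0, chg = "+"),
      L("O1", "O", d, 0, 0, acc = TRUE, chg = "-"),
      L("C1", "C", d + 0.80, 1.04, 0),
      L("O2", "O", d + 2.03, 1.49, 0, acc = TRUE, chg = "-"),
      L("C3", "C", d + 0.23, 2.44, 0, hp = TRUE))),
    salt_negative = list(atoms = {
      ## quaternary ammonium ligand: charged but no N-H donor
      n1 <- c(d, 0, 0)
      dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                    c(-1, -1, 1)) / sqrt(3)
      me <- sweep(1.49 * dirs, 2, n1, "+")
      rbind(
        P("ASP", "CB",  "C", -1.38, -0.43, 0, hp = TRUE),
        P("ASP", "CG",  "C", -0.88, 0.97, 0),
        P("ASP", "OD1", "O",  0.0, 0, 0, acc = TRUE, chg = "-"),
        P("ASP", "OD2", "O", -1.83, 1.87, 0, acc = TRUE, chg = "-"),
        L("N1", "N", n1[1], n1[2], n1[3], chg = "+"),
        L("C1", "C", me[1, 1], me[1, 2], me[1, 3]),
        L("C2", "C", me[2, 1], me[2, 2], me[2, 3]),
        L("C3", "C", me[3, 1], me[3, 2], me[3, 3]),
        L("C4", "C", me[4, 1], me[4, 2], me[4, 3]))
    }),
    metal = list(atoms = rbind(
      P("ZN", "ZN", "ZN", 0, 0, 0, chg = "+", met = TRUE),
      L("O1", "O", d, 0, 0, acc = TRUE, don = TRUE),
      L("C1", "C", d + 0.86, 0.91, 0),
      L("C2", "C", d + 2.37, 0.91, 0, hp = TRUE))),
    aromatic_f2f = {
      his <- ring_vertices(c(0, 0, 0), c(1, 0, 0), 1.17, 5)
      nrm <- c(cos(ang * pi / 180), 0, sin(ang * pi / 180))
      tri <- ring_vertices(c(d, 0, 0), nrm, 1.338, 6)
      his_names <- c("CG", "ND1", "CE1", "NE2", "CD2")
      his_el <- c("C", "N", "C", "N", "C")
      tri_el <- c("N", "C", "N", "C", "N", "C")
      atoms <- rbind(
        do.call(rbind, lapply(1:5, function(i)
          station_atom("protein", "HIS", his_names[i], his_el[i],
                       his[i, 1], his[i, 2], his[i, 3],
                       don = his_names[i] == "NE2",
                       acc = his_names[i] == "ND1", arom = TRUE))),
        do.call(rbind, lapply(1:6, function(i)
          station_atom("ligand", "LIG", paste0("R", i), tri_el[i],
                       tri[i, 1], tri[i, 2], tri[i, 3],
                       acc = tri_el[i] == "N", arom = TRUE))))
      list(atoms = atoms,
           prot_ring = his_names, lig_ring = paste0("R", 1:6))
    },
    aromatic_e2f = {
      his <- ring_vertices(c(0, 0, 0), c(1, 0, 0), 1.17, 5)
      a <- ang * pi / 180
      nrm <- c(cos(a), 0, sin(a))
      ## phase chosen so a carbon vertex points back toward the protein ring
      tri <- ring_vertices(c(d, 0, 0), nrm, 1.338, 6, phase = 90)
      his_names <- c("CG", "ND1", "CE1", "NE2", "CD2")
      his_el <- c("C", "N", "C", "N", "C")
      ## vertex closest to the protein must be carbon; alternate from there
      closest <- which.min(tri[, 1])
      tri_el <- rep(c("C", "N"), 3)[((seq_len(6) - closest) %% 6) + 1]
      atoms <- rbind(
        do.call(rbind, lapply(1:5, function(i)
          station_atom("protein", "HIS", his_names[i], his_el[i],
                       his[i, 1], his[i, 2], his[i, 3],
                       don = his_names[i] == "NE2",
                       acc = his_names[i] == "ND1", arom = TRUE))),
        do.call(rbind, lapply(1:6, function(i)
          station_atom("ligand", "LIG", paste0("R", i), tri_el[i],
                       tri[i, 1], tri[i, 2], tri[i, 3],
                       acc = tri_el[i] == "N", arom = TRUE))))
      list(atoms = atoms,
           prot_ring = his_names, lig_ring = paste0("R", 1:6))
    },
    stop("unknown interaction type: ", type))
}

## generator-side self-check: scan every protein-ligand pair with the
## generator's own flags; any geometric hit that is not the station's
## planted type (or crosses stations) makes the spec unplantable
check_planted <- function(atoms, stations, params) {
  pa <- atoms[atoms$side == "protein", ]
  la <- atoms[atoms$side == "ligand", ]
  if (!nrow(pa) || !nrow(la)) return(invisible(TRUE))
  slack <- 0.2
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(la))) {
    dd <- vec_norm(c(pa$x[i] - la$x[j], pa$y[i] - la$y[j],
                     pa$z[i] - la$z[j]))
    hits <- character(0)
    if (pa$hp[i] && la$hp[j] && dd <= params$d_hphob + slack)
      hits <- c(hits, "hydrophobic")
    if (pa$don[i] && !pa$met[i] && la$acc[j] && dd <= params$d_hbond + slack)
      hits <- c(hits, "hbond_donor")
    if (pa$acc[i] && la$don[j] && dd <= params$d_hbond + slack)
      hits <- c(hits, "hbond_acceptor")
    if (pa$chg[i] == "+" && !pa$met[i] && la$chg[j] == "-" &&
        dd <= params$d_salt + slack)
      hits <- c(hits, "salt_positive")
    if (pa$chg[i] == "-" && la$chg[j] == "+" && dd <= params$d_salt + slack)
      hits <- c(hits, "salt_negative")
    if (pa$met[i] && (la$chg[j] == "-" || la$acc[j]) &&
        dd <= params$d_metal + slack)
      hits <- c(hits, "metal")
    for (h in hits) {
      same <- pa$station[i] == la$station[j]
      if (!same || h != stations[pa$station[i]])
        stop("unplantable spec: unintended ", h, " contact between ",
             pa$name[i], " and ", la$name[j], " at ", round(dd, 2), " A")
    }
    if (dd < 1.5 && pa$station[i] != la$station[j])
      stop("unplantable spec: steric clash at ", round(dd, 2), " A")
  }
  invisible(TRUE)
}

#' Generate a miniature planted-complex PDB fixture
#'
#' Builds a synthetic PDB structure in which each requested interaction
#' type is planted as an isolated probe-group pair (stations 30 Angstrom
#' apart), verifies with the generator's own arithmetic that no unintended
#' contact can fire within the default cutoffs plus slack, applies a seeded
#' random rigid motion to the whole complex, and returns the PDB text
#' together with the expected residue-mode interaction keys.
#'
#' @param spec a [planted_complex_spec()].
#' @param seed seed for the rigid motion.
#' @param target_id,fragment_id identifiers stamped into the expected keys.
#' @param params geometry parameters the margins are validated against.
#' @return List with `pdb` (character vector of PDB lines),
#'   `expected_keys` (residue-mode keys `"target|site|type"`),
#'   `ligand_selector` (`"LIG"`), `target_id`, `fragment_id`.
#' @export
generate_complex_fixture <- function(spec, seed = 0L,
                                     target_id = "SYNTARG",
                                     fragment_id = "SYNFRAG",
                                     params = geometry_params()) {
  stopifnot(inherits(spec, "planted_complex_spec"))
  cutoff <- c(hydrophobic = params$d_hphob, aromatic_f2f = params$d_ring,
              aromatic_e2f = params$d_ring, hbond_donor = params$d_hbond,
              hbond_acceptor = params$d_hbond, salt_positive = params$d_salt,
              salt_negative = params$d_salt, metal = params$d_metal)
  n_st <- length(spec$types)
  all_atoms <- NULL
  rings <- list()
  expected <- character(0)
  for (s in seq_len(n_st)) {
    type <- spec$types[s]; d <- spec$distances[s]; ang <- spec$angles[s]
    if (d < 1.5 || d > cutoff[type] - 0.3)
      stop("unplantable spec: ", type, " distance ", d,
           " outside (1.5, ", cutoff[type] - 0.3, ")")
    if (type == "aromatic_f2f" && !(ang <= params$a_parallel - 10))
      stop("unplantable spec: face-to-face angle ", ang,
           " too close to the parallel boundary")
    if (type == "aromatic_e2f" &&
        !(ang >= params$a_perp_lo + 10 && ang <= params$a_perp_hi - 10))
      stop("unplantable spec: edge-to-face angle ", ang,
           " too close to the perpendicular band edges")
    st <- build_station(type, d, ang)
    at <- st$atoms
    at$y <- at$y + 30 * (s - 1)
    at$station <- s
    at$resno <- ifelse(at$side == "protein", s, 1L)
    all_atoms <- rbind(all_atoms, at)
    prot_res <- unique(at$resname[at$side == "protein"])
    expected <- c(expected, sprintf("%s|A:%s:%d|%s", target_id,
                                    prot_res, s, type))
  }
  ## decoys: protein-side glycine CA carbons and three ligand carbons, all
  ## at least 8 A (beyond every cutoff) from the stations and each other
  if (spec$decoy_atoms > 0) {
    for (jj in seq_len(spec$decoy_atoms)) {
      dat <- station_atom("protein", "GLY", "CA", "C", 5 * jj, -50, 0)
      dat$station <- 0L; dat$resno <- 100L + jj
      all_atoms <- rbind(all_atoms, dat)
    }
  }
  for (jj in 1:3) {
    dat <- station_atom("ligand", "LIG", paste0("D", jj), "C",
                        5 * jj, -40, 0, hp = TRUE)
    dat$station <- -jj; dat$resno <- 1L
    all_atoms <- rbind(all_atoms, dat)
  }
  ## ligand atoms share one LIG residue: names must be unique across
  ## stations (PDB atom names identify atoms within a residue)
  lig_rows <- which(all_atoms$side == "ligand")
  all_atoms$name[lig_rows] <- paste0("L", seq_along(lig_rows))

  stations <- stats::setNames(spec$types, seq_len(n_st))
  check_planted(all_atoms, stations, params)

  ## seeded random rigid motion of the whole complex
  set.seed(seed)
  ax <- unit(stats::rnorm(3))
  R <- rotation_matrix(ax, stats::runif(1, 0, 360))
  tr <- stats::runif(3, -20, 20)
  xyz <- as.matrix(all_atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, tr, "+")

  is_lig <- all_atoms$side == "ligand"
  chain <- ifelse(is_lig, "L", "A")
  lines <- sprintf(
    "%s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(all_atoms$resname %in% c("LIG", "ZN"), "HETATM", "ATOM  "),
    seq_len(nrow(all_atoms)),
    ifelse(nchar(all_atoms$name) < 4, paste0(" ", all_atoms$name),
           all_atoms$name),
    all_atoms$resname, chain, all_atoms$resno,
    xyz[, 1], xyz[, 2], xyz[, 3], 1, 10, all_atoms$element)
  list(pdb = c(lines, "END"),
       expected_keys = sort(expected),
       ligand_selector = "LIG",
       target_id = target_id, fragment_id = fragment_id)
}
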