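test_that("a planted backbone H-bond is detected at 2.9 Angstrom", {
  ## formamide fixture: ligand carbonyl O 2.9 A from Gly10 backbone N
  cx <- load_complex(paste(formamide_fixture(), collapse = "\n"),
                     "T1", "F1", "LIG")
  contacts <- detect_interactions(cx)
  hb <- contacts[contacts$type == "hbond_donor", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$protein_res, "A:GLY:10")
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
})

test_that("each planted single-interaction fixture yields exactly its key", {
  for (tp in names(interaction_types())) {
    fx <- generate_complex_fixture(planted_complex_spec(tp), seed = 11)
    cx <- load_complex(paste(fx$pdb, collapse = "\n"), fx$target_id,
                       fx$fragment_id, fx$ligand_selector)
    expect_identical(ifp_keys(residue_ifp(cx)), fx$expected_keys,
                     label = tp)
  }
})

test_that("distant ligands produce an empty contact list and zero bits", {
  fx <- generate_complex_fixture(
    planted_complex_spec(character(0), distances = numeric(0),
                         angles = numeric(0), decoy_atoms = 20), seed = 2)
  cx <- load_complex(paste(fx$pdb, collapse = "\n"), fx$target_id,
                     fx$fragment_id, fx$ligand_selector)
  expect_equal(nrow(detect_interactions(cx)), 0)
  fp <- residue_ifp(cx)
  expect_equal(sum(fp$bits), 0)
  expect_length(ifp_keys(fp), 0)
})

test_that("residue mode ORs atoms while atomic mode resolves them", {
  ## quaternary ammonium between both Asp carboxylate oxygens
  txt <- c(pdb_line("ATOM", 1, "CG", "ASP", "A", 3, -0.88, 0.97, 0),
           pdb_line("ATOM", 2, "OD1", "ASP", "A", 3, 0, 0, 0,
                    element = "O"),
           pdb_line("ATOM", 3, "OD2", "ASP", "A", 3, -1.83, 1.87, 0,
                    element = "O"),
           pdb_line("HETATM", 4, "N1", "LIG", "L", 1, 2.0, 1.6, 0,
                    element = "N"),
           pdb_line("HETATM", 5, "C1", "LIG", "L", 1, 2.86, 2.46, 0.86,
                    element = "C"),
           pdb_line("HETATM", 6, "C2", "LIG", "L", 1, 2.86, 0.74, -0.86,
                    element = "C"),
           pdb_line("HETATM", 7, "C3", "LIG", "L", 1, 1.14, 2.46, -0.86,
                    element = "C"),
           pdb_line("HETATM", 8, "C4", "LIG", "L", 1, 1.14, 0.74, 0.86,
                    element = "C"),
           "END")
  cx <- load_complex(paste(txt, collapse = "\n"), "T1", "F1", "LIG")
  n1 <- cx$atoms[cx$atoms$name == "N1", ]
  expect_equal(n1$charge, "+")
  rfp <- residue_ifp(cx)
  afp <- atomic_ifp(cx)
  expect_equal(sum(rfp$bits), 1)      # one residue x one type
  expect_equal(sum(afp$bits), 2)      # both carboxylate oxygens
  expect_identical(ifp_keys(collapse_to_residue(afp)), ifp_keys(rfp))
})

test_that("atomic bits collapse to residue bits on randomized fixtures", {
  types <- names(interaction_types())
  for (s in 1:25) {
    set.seed(1000 + s)
    tp <- sample(types, sample(1:4, 1))
    fx <- generate_complex_fixture(planted_complex_spec(tp), seed = s)
    cx <- load_complex(paste(fx$pdb, collapse = "\n"), fx$target_id,
                       fx$fragment_id, fx$ligand_selector)
    afp <- atomic_ifp(cx)
    expect_identical(ifp_keys(collapse_to_residue(afp)),
                     ifp_keys(residue_ifp(cx)))
  }
})

test_that("fingerprints are invariant under rigid motion", {
  fx <- generate_complex_fixture(planted_complex_spec("all"), seed = 9)
  cx <- load_complex(paste(fx$pdb, collapse = "\n"), fx$target_id,
                     fx$fragment_id, fx$ligand_selector)
  for (s in 1:5) {
    set.seed(s)
    R <- fragrank:::rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 360))
    tr <- stats::runif(3, -30, 30)
    cx2 <- transform_complex(cx, R, tr)
    expect_identical(ifp_keys(residue_ifp(cx2)), ifp_keys(residue_ifp(cx)))
    expect_identical(ifp_keys(atomic_ifp(cx2)), ifp_keys(atomic_ifp(cx)))
  }
})

test_that("enlarging distance cutoffs never removes a contact", {
  fx <- generate_complex_fixture(planted_complex_spec("all"), seed = 4)
  cx <- load_complex(paste(fx$pdb, collapse = "\n"), fx$target_id,
                     fx$fragment_id, fx$ligand_selector)
  base <- geometry_params()
  wide <- geometry_params(d_hphob = 5, d_hbond = 4.5, d_salt = 5,
                          d_metal = 4, d_ring = 6)
  k_base <- ifp_keys(residue_ifp(cx, base))
  k_wide <- ifp_keys(residue_ifp(cx, wide))
  expect_true(all(k_base %in% k_wide))
})

test_that("IFP Tanimoto follows set semantics with its edge conventions", {
  mkfp <- function(sites, types, target = "T1", mode = "residue") {
    all_types <- names(interaction_types())
    usites <- sort(unique(sites))
    bits <- matrix(0L, length(usites), 8,
                   dimnames = list(usites, all_types))
    bits[cbind(match(sites, usites), match(types, all_types))] <- 1L
    structure(list(target_id = target, fragment_id = "F", mode = mode,
                   sites = usites, bits = bits),
              class = "interaction_fingerprint")
  }
  a <- mkfp(c("r1", "r2", "r3"), rep("hydrophobic", 3))
  expect_equal(ifp_tanimoto(a, a), 1)
  b <- mkfp(c("r4", "r5"), rep("hydrophobic", 2))
  expect_equal(ifp_tanimoto(a, b), 0)
  ## bits {r1,r2,r3} vs {r2,r3,r4} -> 2/4
  d <- mkfp(c("r2", "r3", "r4"), rep("hydrophobic", 3))
  expect_equal(ifp_tanimoto(a, d), 0.5)
  expect_equal(ifp_tanimoto(a, d), ifp_tanimoto(d, a))
  ## both empty -> 0 by convention
  z <- mkfp(character(0), character(0))
  expect_equal(ifp_tanimoto(z, z), 0)
  expect_error(ifp_tanimoto(a, mkfp("r1", "hydrophobic", target = "T2")),
               "cross-target")
  amode <- mkfp("r1:CA", "hydrophobic", mode = "atomic")
  expect_error(ifp_tanimoto(a, amode), "mode")
})

test_that("geometry params validate and round-trip through YAML", {
  p <- geometry_params(d_hbond = 3.2)
  path <- tempfile(fileext = ".yaml")
  write_geometry_params(p, path)
  p2 <- read_geometry_params(path)
  expect_equal(unclass(p), unclass(p2))
  writeLines("d_bogus: 3", path)
  expect_error(read_geometry_params(path), "unknown geometry parameter")
})
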