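test_that("a minimal complex parses with the expected composition", {
  cx <- load_complex(paste(formamide_fixture(), collapse = "\n"),
                     "T1", "F1", "LIG")
  expect_s3_class(cx, "complex_structure")
  prot <- cx$atoms[!cx$atoms$is_ligand, ]
  expect_equal(length(unique(prot$res_id)), 2)
  expect_equal(sum(cx$atoms$is_ligand), 4)
  expect_false(any(cx$atoms$resname == "HOH"))
})

test_that("highest-occupancy altloc is retained, ties go to A", {
  cx <- load_complex(paste(altloc_fixture(), collapse = "\n"),
                     "T1", "F1", "LIG")
  ca <- cx$atoms[cx$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$occupancy, 0.7)
  expect_equal(ca$x, 1.4)
})

test_that("ligand selection errors are specific", {
  txt <- paste(formamide_fixture(), collapse = "\n")
  expect_error(load_complex(txt, "T1", "F1", "XYZ"), "ligand not found")
  expect_error(load_complex(txt, "T1", "F1", "GLY"), "ambiguous selection")
  two_copy <- c(formamide_fixture()[1:12],
                pdb_line("HETATM", 20, "C5", "LIG", "L", 2, 20, 0, 0,
                         element = "C"),
                pdb_line("HETATM", 21, "C6", "LIG", "L", 2, 21.5, 0, 0,
                         element = "C"),
                pdb_line("HETATM", 22, "O5", "LIG", "L", 2, 20, 1.2, 0,
                         element = "O"), "END")
  expect_error(load_complex(paste(two_copy, collapse = "\n"),
                            "T1", "F1", "LIG"), "copies")
  sels <- ligand_copies(paste(two_copy, collapse = "\n"), "LIG")
  expect_length(sels, 2)
  cx <- load_complex(paste(two_copy, collapse = "\n"), "T1", "F1", sels[1])
  expect_equal(sum(cx$atoms$is_ligand), 4)
})

test_that("template typing assigns the canonical pharmacophore flags", {
  txt <- c(pdb_line("ATOM", 1, "CB", "LYS", "A", 5, 0, 0, 0),
           pdb_line("ATOM", 2, "NZ", "LYS", "A", 5, 1.5, 0, 0),
           pdb_line("ATOM", 3, "CG", "PHE", "A", 6, 10, 0, 0),
           pdb_line("ATOM", 4, "OD1", "ASP", "A", 7, 20, 0, 0,
                    element = "O"),
           pdb_line("HETATM", 5, "ZN", "ZN", "A", 90, 30, 0, 0,
                    element = "ZN"),
           pdb_line("HETATM", 6, "C1", "LIG", "L", 1, 40, 0, 0,
                    element = "C"),
           pdb_line("HETATM", 7, "C2", "LIG", "L", 1, 41.5, 0, 0,
                    element = "C"),
           pdb_line("HETATM", 8, "O1", "LIG", "L", 1, 40, 1.2, 0,
                    element = "O"),
           "END")
  cx <- load_complex(paste(txt, collapse = "\n"), "T1", "F1", "LIG")
  a <- cx$atoms
  nz <- a[a$name == "NZ", ]
  expect_true(nz$donor); expect_equal(nz$charge, "+")
  cg <- a[a$name == "CG" & a$resname == "PHE", ]
  expect_true(cg$aromatic); expect_true(cg$hydrophobic)
  od1 <- a[a$name == "OD1", ]
  expect_equal(od1$charge, "-"); expect_true(od1$acceptor)
  zn <- a[a$element == "ZN", ]
  expect_true(zn$is_metal); expect_equal(zn$charge, "+")
  expect_false(zn$donor)
})

test_that("unknown residues fall back to element typing with a message", {
  txt <- c(pdb_line("ATOM", 1, "N1", "XXX", "A", 5, 0, 0, 0,
                    element = "N"),
           pdb_line("ATOM", 2, "O1", "XXX", "A", 5, 1.5, 0, 0,
                    element = "O"),
           pdb_line("HETATM", 3, "C1", "LIG", "L", 1, 20, 0, 0,
                    element = "C"),
           pdb_line("HETATM", 4, "C2", "LIG", "L", 1, 21.5, 0, 0,
                    element = "C"),
           pdb_line("HETATM", 5, "C3", "LIG", "L", 1, 20, 1.5, 0,
                    element = "C"),
           "END")
  expect_message(cx <- load_complex(paste(txt, collapse = "\n"),
                                    "T1", "F1", "LIG"), "fallback")
  a <- cx$atoms
  expect_true(a$donor[a$name == "N1"])
  expect_true(a$acceptor[a$name == "O1"])
})

test_that("write/re-parse round-trip preserves atoms, coords and typing", {
  fx <- generate_complex_fixture(planted_complex_spec("all"), seed = 5)
  cx <- load_complex(paste(fx$pdb, collapse = "\n"), fx$target_id,
                     fx$fragment_id, fx$ligand_selector)
  txt2 <- write_complex_pdb(cx)
  cx2 <- load_complex(paste(txt2, collapse = "\n"), fx$target_id,
                      fx$fragment_id, fx$ligand_selector)
  expect_equal(nrow(cx$atoms), nrow(cx2$atoms))
  expect_equal(round(cx$atoms$x, 3), round(cx2$atoms$x, 3))
  expect_equal(round(cx$atoms$y, 3), round(cx2$atoms$y, 3))
  expect_equal(round(cx$atoms$z, 3), round(cx2$atoms$z, 3))
  flags <- c("hydrophobic", "donor", "acceptor", "aromatic", "charge",
             "is_metal")
  expect_equal(cx$atoms[, flags], cx2$atoms[, flags])
})

test_that("dataset assembly applies the tested-on filter and unions", {
  mk <- function(types, target, frag, seed)
    load_complex(paste(generate_complex_fixture(
      planted_complex_spec(types), seed = seed,
      target_id = target, fragment_id = frag)$pdb, collapse = "\n"),
      target, frag, "LIG")
  tested <- matrix(FALSE, 3, 10,
                   dimnames = list(c("F1", "F2", "F3"), paste0("T", 1:10)))
  tested["F1", 1:7] <- TRUE
  tested["F2", 1:7] <- TRUE
  tested["F3", 1:5] <- TRUE
  cxs <- list(mk("hydrophobic", "T1", "F1", 1),
              mk(c("hbond_donor", "metal"), "T2", "F1", 2),
              mk("salt_positive", "T1", "F2", 3))
  ds <- build_dataset(cxs, tested, min_tested = 7)
  expect_equal(nrow(ds$fragments), 2)   # F3 screened on too few targets
  expect_setequal(ds$fragments$fragment_id, c("F1", "F2"))
  ## two complexes of F1 union their keys
  expect_length(ds$profiles$residue$F1, 3)
  expect_length(ds$profiles$residue$F2, 1)
  ## raising min_tested never increases the fragment count
  n_prev <- Inf
  for (mt in c(0, 5, 7, 8)) {
    n_now <- nrow(build_dataset(cxs, tested, min_tested = mt)$fragments)
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
  ## a complex on an untested pair is a hard inconsistency
  cxs_bad <- c(cxs, list(mk("hydrophobic", "T9", "F3", 4)))
  expect_error(build_dataset(cxs_bad, tested, min_tested = 0),
               "untested")
})

test_that("profile union over copies never removes keys", {
  mk <- function(types, seed, frag = "F1")
    load_complex(paste(generate_complex_fixture(
      planted_complex_spec(types), seed = seed, target_id = "T1",
      fragment_id = frag)$pdb, collapse = "\n"), "T1", frag, "LIG")
  tested <- matrix(TRUE, 1, 1, dimnames = list("F1", "T1"))
  one <- build_dataset(list(mk(c("hydrophobic", "hbond_donor"), 1)),
                       tested, 0)
  both <- build_dataset(list(mk(c("hydrophobic", "hbond_donor"), 1),
                             mk(c("hbond_donor", "salt_negative"), 2)),
                        tested, 0)
  expect_true(all(one$profiles$residue$F1 %in% both$profiles$residue$F1))
  expect_setequal(
    both$profiles$residue$F1,
    union(ifp_keys(residue_ifp(mk(c("hydrophobic", "hbond_donor"), 1))),
          ifp_keys(residue_ifp(mk(c("hbond_donor", "salt_negative"), 2)))))
})

test_that("manifest JSON round-trips a dataset", {
  gen <- generate_binding_matrix(synthetic_spec(n_fragments = 30,
                                                n_targets = 3, seed = 4))
  path <- tempfile(fileext = ".json")
  write_dataset_manifest(gen$dataset, path)
  ds2 <- read_dataset_manifest(path)
  expect_identical(gen$dataset$profiles, ds2$profiles)
  expect_identical(gen$dataset$tested, ds2$tested)
  expect_identical(gen$dataset$fragments$fragment_id,
                   ds2$fragments$fragment_id)
})

test_that("tested-matrix CSV reads with absent pairs as untested", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("fragment_id,target_id,tested",
               "F1,T1,1", "F1,T2,0", "F2,T1,1"), path)
  m <- read_tested_matrix(path)
  expect_true(m["F1", "T1"])
  expect_false(m["F1", "T2"])
  expect_false(m["F2", "T2"])   # absent -> not tested
})
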