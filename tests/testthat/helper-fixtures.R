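## Hand-built miniature PDB fixtures and independent brute-force oracles.

pdb_line <- function(record, serial, name, resname, chain, resno, x, y, z,
                     occ = 1, altloc = " ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resname, chain, resno, x, y, z, occ, 10, element)
}

## two glycine residues + a formamide-like 4-heavy-atom ligand + a water
formamide_fixture <- function() {
  c(pdb_line("ATOM", 1, "N", "GLY", "A", 10, 0, 0, 0),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 10, 1.47, 0, 0),
    pdb_line("ATOM", 3, "C", "GLY", "A", 10, 2.2, 0, 1.2),
    pdb_line("ATOM", 4, "O", "GLY", "A", 10, 1.7, 0, 2.35),
    pdb_line("ATOM", 5, "N", "GLY", "A", 11, 3.5, 0, 1.4),
    pdb_line("ATOM", 6, "CA", "GLY", "A", 11, 4.9, 0, 1.6),
    pdb_line("ATOM", 7, "C", "GLY", "A", 11, 5.6, 0, 2.9),
    pdb_line("ATOM", 8, "O", "GLY", "A", 11, 5.0, 0, 4.0),
    ## formamide-like ligand: O=C-N plus a methyl, O 2.9 A from Gly10 N
    pdb_line("HETATM", 9, "O1", "LIG", "L", 1, -2.9, 0, 0, element = "O"),
    pdb_line("HETATM", 10, "C1", "LIG", "L", 1, -3.76, 0.91, 0,
             element = "C"),
    pdb_line("HETATM", 11, "N1", "LIG", "L", 1, -5.08, 0.62, 0,
             element = "N"),
    pdb_line("HETATM", 12, "C2", "LIG", "L", 1, -3.3, 2.33, 0,
             element = "C"),
    pdb_line("HETATM", 13, "O", "HOH", "W", 201, 8, 8, 8, element = "O"),
    "END")
}

altloc_fixture <- function() {
  c(pdb_line("ATOM", 1, "N", "GLY", "A", 1, 0, 0, 0),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 1.4, 0, 0, occ = 0.7,
             altloc = "A"),
    pdb_line("ATOM", 3, "CA", "GLY", "A", 1, 1.5, 0.1, 0, occ = 0.3,
             altloc = "B"),
    pdb_line("HETATM", 4, "C1", "LIG", "L", 1, 9, 0, 0, element = "C"),
    pdb_line("HETATM", 5, "C2", "LIG", "L", 1, 10.5, 0, 0, element = "C"),
    pdb_line("HETATM", 6, "O1", "LIG", "L", 1, 9, 1.2, 0, element = "O"),
    "END")
}

## abstract dataset built directly from named key-set profiles
make_profile_dataset <- function(profiles, targets = NULL, smiles = NULL) {
  if (is.null(targets))
    targets <- sort(unique(sub("\\|.*$", "",
                               unlist(profiles, use.names = FALSE))))
  fragments <- data.frame(fragment_id = names(profiles),
                          stringsAsFactors = FALSE)
  if (!is.null(smiles)) fragments$smiles <- smiles
  tested <- matrix(TRUE, length(profiles), length(targets),
                   dimnames = list(names(profiles), targets))
  screen_dataset(fragments, targets, tested, profiles, profiles)
}

## keys "T|s<i>|x" on one target from integer ids
tkeys <- function(ids, target = "T1") sprintf("%s|s%d|x", target, ids)

## the worked 4-fragment instance: A={1,2,3}, B={3,4}, C={5}, D={1,2}
abcd_dataset <- function() {
  make_profile_dataset(list(A = tkeys(1:3), B = tkeys(3:4), C = tkeys(5),
                            D = tkeys(1:2)))
}

## random abstract instance for oracle tests: integer-bitmask profiles
## (universe <= 30 keys so coverage fits machine integers)
rand_instance <- function(seed, max_frags = 15, max_keys = 30) {
  set.seed(seed)
  n <- sample(2:max_frags, 1)
  K <- sample(5:max_keys, 1)
  profiles <- lapply(seq_len(n), function(i)
    sort(sample.int(K, sample(1:min(6, K), 1))))
  names(profiles) <- sprintf("f%02d", seq_len(n))
  profiles
}

bitmask <- function(ids) sum(bitwShiftL(1L, ids - 1L))

popcount <- function(x) {
  n <- 0L
  while (x > 0) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

## brute-force optimal max-coverage value for every k (instances <= ~12)
brute_max_coverage <- function(masks) {
  n <- length(masks)
  vapply(seq_len(n), function(k) {
    best <- 0L
    cmb <- utils::combn(n, k)
    for (ci in seq_len(ncol(cmb))) {
      cov <- Reduce(bitwOr, masks[cmb[, ci]], 0L)
      best <- max(best, popcount(cov))
    }
    best
  }, integer(1))
}

## random on-bit fingerprint sets
rand_fps <- function(seed, n = NULL, nbits = 64) {
  set.seed(seed)
  if (is.null(n)) n <- sample(2:10, 1)
  fps <- lapply(seq_len(n), function(i)
    sort(sample.int(nbits, sample(1:12, 1))))
  names(fps) <- sprintf("m%02d", seq_len(n))
  fps
}
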