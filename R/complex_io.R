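#' Load a protein-fragment complex from PDB text
#'
#' Parses one crystal structure of a fragment bound to a target, separates
#' the ligand from the protein, applies standard crystallographic hygiene
#' (waters and buffer molecules dropped, highest-occupancy alternate
#' location retained, hydrogens ignored) and assigns pharmacophoric atom
#' types to both sides.
#'
#' @param pdb_text character scalar (or vector of lines) of PDB
#'   ATOM/HETATM records, or a path to a `.pdb` file.
#' @param target_id,fragment_id identifiers attached to every interaction
#'   key derived from this structure.
#' @param ligand_selector either a residue name (e.g. `"LIG"`) or a
#'   qualified `"chain:resname:number"` spec. Must match exactly one ligand
#'   copy; use [ligand_copies()] to enumerate qualified selectors when a
#'   fragment bound in several copies.
#' @param crystal_id optional crystal identifier (defaults to
#'   `"target-fragment"`).
#' @param assign_types type the atoms and perceive aromatic rings
#'   (default `TRUE`).
#' @return A `"complex_structure"` object: a list with `target_id`,
#'   `fragment_id`, `crystal_id`, an `atoms` data frame (coordinates,
#'   residue identity, typing flags, `is_ligand`), and `rings` (aromatic
#'   rings of both molecules, each with member rows, centroid, unit normal).
#' @export
load_complex <- function(pdb_text, target_id, fragment_id, ligand_selector,
                         crystal_id = NULL, assign_types = TRUE) {
  path <- pdb_text
  if (length(pdb_text) > 1 || grepl("\n", pdb_text) ||
      !file.exists(pdb_text)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(pdb_text, "\n")), path)
  }
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[!(toupper(a$elesy) %in% c("H", "D")), , drop = FALSE]
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$chain[is.na(a$chain)] <- ""
  a$o[is.na(a$o)] <- 1

  ## altloc: keep highest occupancy per (chain, resno, insert, atom name),
  ## ties resolved toward altloc "A" (then alphabetically)
  grp <- paste(a$chain, a$resno, a$insert, a$resid, a$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(a)), grp), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- a$o[idx]
    cand <- idx[occ == max(occ)]
    cand[order(a$alt[cand])][1]
  }), use.names = FALSE)
  a <- a[sort(keep), , drop = FALSE]

  sel <- parse_ligand_selector(ligand_selector)
  is_lig <- toupper(a$resid) == sel$resname
  if (!is.null(sel$chain)) is_lig <- is_lig & a$chain == sel$chain
  if (!is.null(sel$resno)) is_lig <- is_lig & a$resno == sel$resno
  if (!any(is_lig)) stop("ligand not found: ", ligand_selector)
  if (any(is_lig & a$type == "ATOM"))
    stop("ambiguous selection: ", ligand_selector,
         " matches polymer (protein) records")
  inst <- unique(paste(a$chain[is_lig], a$resno[is_lig], a$insert[is_lig]))
  if (length(inst) > 1)
    stop("ligand selector '", ligand_selector, "' matches ", length(inst),
         " copies; qualify as chain:resname:number (see ligand_copies())")

  drop <- !is_lig & toupper(a$resid) %in% c(WATER_RESNAMES, BUFFER_RESNAMES)
  a <- a[!drop, , drop = FALSE]
  is_lig <- is_lig[!drop]

  atoms <- data.frame(
    serial = a$eleno, name = a$elety, element = toupper(a$elesy),
    x = a$x, y = a$y, z = a$z, altloc = a$alt, occupancy = a$o,
    chain = a$chain, resno = a$resno, insert = a$insert,
    resname = toupper(a$resid), is_ligand = is_lig,
    stringsAsFactors = FALSE)
  atoms$res_id <- residue_id(atoms)
  atoms$hydrophobic <- atoms$donor <- atoms$acceptor <- atoms$aromatic <-
    atoms$is_metal <- FALSE
  atoms$charge <- "0"

  if (sum(atoms$is_ligand) < 3)
    stop("ligand has fewer than 3 heavy atoms")
  if (!any(!atoms$is_ligand))
    stop("no protein atoms in structure")

  str <- structure(list(
    target_id = target_id, fragment_id = fragment_id,
    crystal_id = if (is.null(crystal_id))
      paste(target_id, fragment_id, sep = "-") else crystal_id,
    atoms = atoms, rings = list()), class = "complex_structure")
  if (assign_types) str <- assign_atom_types(str) else str
}

## stable residue identity string: "chain:resname:number[insertion]"
residue_id <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resname, ":", atoms$resno, atoms$insert)
}

parse_ligand_selector <- function(sel) {
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1) return(list(resname = toupper(parts)))
  if (length(parts) == 3)
    return(list(chain = parts[1], resname = toupper(parts[2]),
                resno = as.integer(parts[3])))
  stop("ligand selector must be 'RESNAME' or 'chain:RESNAME:number'")
}

#' Enumerate ligand copies in a PDB file
#'
#' Returns one qualified `"chain:resname:number"` selector per copy of the
#' given residue name, so that multiply-bound fragments can be loaded as
#' separate [load_complex()] structures (profiles are unioned over copies by
#' [build_dataset()]).
#'
#' @param pdb_text PDB text or path as in [load_complex()].
#' @param resname ligand residue name.
#' @return Character vector of qualified selectors.
#' @export
ligand_copies <- function(pdb_text, resname) {
  path <- pdb_text
  if (length(pdb_text) > 1 || grepl("\n", pdb_text) ||
      !file.exists(pdb_text)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(pdb_text, "\n")), path)
  }
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE, verbose = FALSE)
  a <- pdb$atom[toupper(pdb$atom$resid) == toupper(resname), , drop = FALSE]
  unique(paste(a$chain, toupper(a$resid), a$resno, sep = ":"))
}

#' Assign pharmacophoric atom types and perceive aromatic rings
#'
#' Protein atoms are typed by residue template (e.g. Lys NZ positive and
#' donor, Asp OD1/OD2 negative acceptors, backbone N donor / O acceptor,
#' His/Phe/Tyr/Trp ring membership); metals are flagged `is_metal` with
#' positive charge. Ligand atoms are typed from distance-inferred
#' connectivity; ligand aromatic rings are planar 5/6-cycles. Unknown
#' protein residues fall back to element rules with a message (never fatal).
#'
#' @param structure a `"complex_structure"`.
#' @return The structure with typing flags and `rings` populated.
#' @export
assign_atom_types <- function(structure) {
  stopifnot(inherits(structure, "complex_structure"))
  atoms <- structure$atoms
  atoms$hydrophobic <- atoms$donor <- atoms$acceptor <- atoms$aromatic <-
    atoms$is_metal <- FALSE
  atoms$charge <- "0"
  atoms <- type_protein_atoms(atoms)
  lt <- type_ligand_atoms(atoms)
  atoms <- lt$atoms
  ## metals never donate hydrogens
  atoms$donor[atoms$is_metal] <- FALSE

  rings <- list()
  ## protein rings from templates
  tmpl <- protein_templates()
  prot_res <- unique(atoms$res_id[!atoms$is_ligand])
  for (rid in prot_res) {
    rows <- which(atoms$res_id == rid & !atoms$is_ligand)
    tp <- tmpl[[atoms$resname[rows[1]]]]
    if (is.null(tp$rings)) next
    for (rr in tp$rings) {
      mem <- rows[match(rr, atoms$name[rows])]
      if (anyNA(mem)) next
      pl <- ls_plane(as.matrix(atoms[mem, c("x", "y", "z")]))
      rings[[length(rings) + 1]] <- list(members = mem,
        centroid = pl$centroid, normal = pl$normal, is_ligand = FALSE)
    }
  }
  for (r in lt$rings) {
    pl <- ls_plane(as.matrix(atoms[r, c("x", "y", "z")]))
    rings[[length(rings) + 1]] <- list(members = r,
      centroid = pl$centroid, normal = pl$normal, is_ligand = TRUE)
  }
  structure$atoms <- atoms
  structure$rings <- rings
  structure
}

#' Write a complex back to PDB text
#'
#' @param structure a `"complex_structure"`.
#' @param path optional output file.
#' @return The PDB text (character vector of lines), invisibly if `path`
#'   given.
#' @export
write_complex_pdb <- function(structure, path = NULL) {
  a <- structure$atoms
  rec <- ifelse(a$resname %in% names(protein_templates()), "ATOM  ", "HETATM")
  lines <- sprintf(
    "%s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, a$serial,
    ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
    ifelse(a$altloc == "", " ", a$altloc),
    a$resname, a$chain, a$resno,
    ifelse(a$insert == "", " ", a$insert),
    a$x, a$y, a$z, a$occupancy, 10, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Rigidly transform a complex
#'
#' Applies `x -> R x + t` to every atom and re-derives ring centroids and
#' normals. Interaction fingerprints are invariant under such motions.
#'
#' @param structure a `"complex_structure"`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric.
#' @return The transformed structure.
#' @export
transform_complex <- function(structure, rotation = diag(3),
                              translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2, -translation)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  assign_atom_types(structure)
}

#' Read a fragment catalogue CSV
#'
#' @param path CSV with columns `fragment_id,smiles`.
#' @return Data frame with those columns.
#' @export
read_fragment_catalogue <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("fragment_id", "smiles") %in% names(df)))
  df[, c("fragment_id", "smiles")]
}

#' Read a tested-on matrix CSV
#'
#' Long-format sidecar recording which fragments were screened against which
#' targets. A fragment-target pair absent from the file means "not tested".
#'
#' @param path CSV with columns `fragment_id,target_id,tested` (0/1).
#' @param fragments,targets optional identifier vectors fixing row/column
#'   order (defaults to order of appearance).
#' @return Logical matrix, fragments x targets.
#' @export
read_tested_matrix <- function(path, fragments = NULL, targets = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("fragment_id", "target_id", "tested") %in% names(df)))
  if (is.null(fragments)) fragments <- unique(df$fragment_id)
  if (is.null(targets)) targets <- unique(df$target_id)
  m <- matrix(FALSE, length(fragments), length(targets),
              dimnames = list(fragments, targets))
  hit <- df$tested != 0
  m[cbind(match(df$fragment_id[hit], fragments),
          match(df$target_id[hit], targets))] <- TRUE
  m
}

#' Construct a screen dataset
#'
#' Low-level constructor validating the dataset invariants: every fragment
#' was tested on at least `min_tested` targets, the targets a fragment's
#' profile mentions are a subset of its tested targets, and never-bound
#' fragments have empty profiles.
#'
#' @param fragments data frame with at least `fragment_id` (and optionally
#'   `smiles`).
#' @param targets character vector of target ids.
#' @param tested logical fragments x targets matrix.
#' @param profiles_residue,profiles_atomic named lists (by fragment id) of
#'   character vectors of interaction keys `"target|site|type"`.
#' @param min_tested the inclusion filter the dataset satisfies.
#' @return A `"screen_dataset"` object.
#' @export
screen_dataset <- function(fragments, targets, tested,
                           profiles_residue, profiles_atomic,
                           min_tested = 0L) {
  stopifnot(is.data.frame(fragments), "fragment_id" %in% names(fragments),
            is.matrix(tested),
            nrow(tested) == nrow(fragments),
            ncol(tested) == length(targets))
  fid <- fragments$fragment_id
  dimnames(tested) <- list(fid, targets)
  profiles_residue <- profiles_residue[fid]
  profiles_atomic <- profiles_atomic[fid]
  names(profiles_residue) <- names(profiles_atomic) <- fid
  profiles_residue <- lapply(profiles_residue, function(x)
    sort(unique(as.character(if (is.null(x)) character(0) else x))))
  profiles_atomic <- lapply(profiles_atomic, function(x)
    sort(unique(as.character(if (is.null(x)) character(0) else x))))

  n_tested <- rowSums(tested)
  if (any(n_tested < min_tested))
    stop("fragment(s) below the min_tested filter: ",
         paste(fid[n_tested < min_tested], collapse = ", "))
  for (f in fid) {
    bt <- key_targets(profiles_residue[[f]])
    bt <- union(bt, key_targets(profiles_atomic[[f]]))
    untested <- setdiff(bt, targets[tested[f, ]])
    if (length(untested))
      stop("fragment ", f, " has interactions on untested target(s): ",
           paste(untested, collapse = ", "))
  }
  fragments$n_tested <- as.integer(n_tested)
  fragments$bound_targets <- vapply(fid, function(f)
    paste(sort(key_targets(profiles_residue[[f]])), collapse = ";"),
    character(1))
  fragments$n_bound <- vapply(strsplit(fragments$bound_targets, ";"),
                              function(x) sum(nzchar(x)), integer(1))
  structure(list(fragments = fragments, targets = targets, tested = tested,
                 profiles = list(residue = profiles_residue,
                                 atomic = profiles_atomic),
                 min_tested = as.integer(min_tested)),
            class = "screen_dataset")
}

## targets mentioned by a key vector ("target|site|type")
key_targets <- function(keys) {
  if (!length(keys)) return(character(0))
  unique(vapply(strsplit(keys, "|", fixed = TRUE), `[[`, character(1), 1))
}

#' @export
print.screen_dataset <- function(x, ...) {
  nb <- sum(x$fragments$n_bound > 0)
  cat("screen_dataset:", nrow(x$fragments), "fragments x",
      length(x$targets), "targets\n")
  cat("  bound:", nb, " never bound:", nrow(x$fragments) - nb,
      " (min_tested =", x$min_tested, ")\n")
  cat("  interaction keys: residue",
      length(unique(unlist(x$profiles$residue))), "/ atomic",
      length(unique(unlist(x$profiles$atomic))), "\n")
  invisible(x)
}

#' Assemble a screen dataset from complex structures
#'
#' Computes residue-mode and atomic-mode interaction profiles for every
#' complex, unions them per fragment (a fragment's functional profile is the
#' set of interaction keys over all its complexes, including multiple copies
#' and targets), applies the tested-on inclusion filter, and validates
#' consistency against the tested-on matrix.
#'
#' @param complexes list of `"complex_structure"` objects.
#' @param tested logical fragments x targets matrix (see
#'   [read_tested_matrix()]); must cover every complex's fragment/target.
#' @param min_tested drop fragments screened on fewer than this many targets.
#' @param params [geometry_params()] for interaction detection.
#' @param catalogue optional data frame `fragment_id,smiles`.
#' @return A `"screen_dataset"`.
#' @export
build_dataset <- function(complexes, tested, min_tested = 7L,
                          params = geometry_params(), catalogue = NULL) {
  stopifnot(is.matrix(tested), !is.null(dimnames(tested)))
  fid_all <- rownames(tested); targets <- colnames(tested)
  prof_r <- stats::setNames(vector("list", length(fid_all)), fid_all)
  prof_a <- stats::setNames(vector("list", length(fid_all)), fid_all)
  for (cx in complexes) {
    f <- cx$fragment_id; t <- cx$target_id
    if (!(f %in% fid_all) || !(t %in% targets))
      stop("complex ", cx$crystal_id, ": fragment or target missing from ",
           "tested matrix")
    if (!tested[f, t])
      stop("data inconsistency: complex ", cx$crystal_id, " has (", f, ", ",
           t, ") marked untested")
    prof_r[[f]] <- union(prof_r[[f]], ifp_keys(residue_ifp(cx, params)))
    prof_a[[f]] <- union(prof_a[[f]], ifp_keys(atomic_ifp(cx, params)))
  }
  keep <- rowSums(tested) >= min_tested
  fragments <- data.frame(fragment_id = fid_all[keep],
                          stringsAsFactors = FALSE)
  if (!is.null(catalogue))
    fragments$smiles <- catalogue$smiles[match(fragments$fragment_id,
                                               catalogue$fragment_id)]
  screen_dataset(fragments, targets, tested[keep, , drop = FALSE],
                 prof_r[keep], prof_a[keep], min_tested = min_tested)
}

#' Write a dataset manifest JSON
#'
#' Serializes a screen dataset (fragments, targets, tested-on matrix, bound
#' targets, profile sizes, and the full interaction-key profiles) so that
#' downstream ranking and evaluation can run from the manifest alone.
#'
#' @param dataset a `"screen_dataset"`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_dataset_manifest <- function(dataset, path) {
  obj <- list(
    min_tested = dataset$min_tested,
    targets = dataset$targets,
    fragments = dataset$fragments,
    tested = lapply(stats::setNames(seq_len(nrow(dataset$tested)),
                                    rownames(dataset$tested)),
                    function(i) dataset$targets[dataset$tested[i, ]]),
    profile_sizes = list(
      residue = vapply(dataset$profiles$residue, length, integer(1)),
      atomic = vapply(dataset$profiles$atomic, length, integer(1))),
    profiles = dataset$profiles)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a dataset manifest JSON
#'
#' @param path manifest written by [write_dataset_manifest()].
#' @return A `"screen_dataset"`.
#' @export
read_dataset_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fragments <- as.data.frame(obj$fragments, stringsAsFactors = FALSE)
  tested <- matrix(FALSE, nrow(fragments), length(obj$targets),
                   dimnames = list(fragments$fragment_id, obj$targets))
  for (f in names(obj$tested))
    tested[f, unlist(obj$tested[[f]])] <- TRUE
  pr <- lapply(obj$profiles$residue, function(x) unlist(x))
  pa <- lapply(obj$profiles$atomic, function(x) unlist(x))
  screen_dataset(fragments[, intersect(c("fragment_id", "smiles"),
                                       names(fragments)), drop = FALSE],
                 obj$targets, tested, pr, pa, min_tested = obj$min_tested)
}
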