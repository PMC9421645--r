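## Interaction fingerprint engine: detects up to eight interaction types
## between a fragment and the protein and renders them as binary
## fingerprints at residue or atom resolution.

#' Detect protein-ligand interactions in a typed complex
#'
#' Applies the geometric rules for the eight interaction types:
#' \describe{
#'   \item{hydrophobic}{hydrophobic heavy atoms (C/S, halogens) within
#'     `d_hphob`.}
#'   \item{hbond_donor / hbond_acceptor}{donor-acceptor heavy-atom distance
#'     \eqn{\le} `d_hbond` (protein as donor, resp. acceptor); detection is
#'     hydrogen-free, so the criterion is distance-only.}
#'   \item{salt_positive / salt_negative}{opposite formal charge classes
#'     within `d_salt` (metals excluded; they have their own type).}
#'   \item{metal}{protein-side metal to ligand anion/acceptor within
#'     `d_metal`.}
#'   \item{aromatic_f2f / aromatic_e2f}{ring centroids within `d_ring` with
#'     interplanar angle \eqn{\le} `a_parallel` (face-to-face) or inside
#'     `[a_perp_lo, a_perp_hi]` (edge-to-face).}
#' }
#'
#' @param structure a typed `"complex_structure"` (see
#'   [assign_atom_types()]).
#' @param params a [geometry_params()] object.
#' @return Data frame with one row per contact: `type`, `protein_res`
#'   (residue id string), `protein_atoms` (comma-joined protein atom names;
#'   all ring members for aromatic contacts), `ligand_atoms`, `distance`.
#'   Zero rows when the ligand makes no contact.
#' @export
detect_interactions <- function(structure, params = geometry_params()) {
  stopifnot(inherits(structure, "complex_structure"),
            inherits(params, "geometry_params"))
  at <- structure$atoms
  li <- which(at$is_ligand)
  pi <- which(!at$is_ligand)
  out <- list()
  emit <- function(type, p_rows, l_rows, dist) {
    out[[length(out) + 1]] <<- data.frame(
      type = type,
      protein_res = at$res_id[p_rows[1]],
      protein_atoms = paste(at$name[p_rows], collapse = ","),
      ligand_atoms = paste(at$name[l_rows], collapse = ","),
      distance = dist, stringsAsFactors = FALSE)
  }
  if (length(li) == 0 || length(pi) == 0) {
    message("detect_interactions: no ligand or no protein atoms; ",
            "empty contact list")
    return(empty_contacts())
  }

  pxyz <- as.matrix(at[pi, c("x", "y", "z")])
  lxyz <- as.matrix(at[li, c("x", "y", "z")])
  ## pairwise distances protein x ligand
  d <- sqrt(pmax(outer(rowSums(pxyz^2), rowSums(lxyz^2), "+") -
                   2 * tcrossprod(pxyz, lxyz), 0))

  pair_rule <- function(pmask, lmask, cutoff, type) {
    hit <- which(outer(pmask, lmask, "&") & d <= cutoff, arr.ind = TRUE)
    if (nrow(hit)) for (k in seq_len(nrow(hit)))
      emit(type, pi[hit[k, 1]], li[hit[k, 2]], d[hit[k, 1], hit[k, 2]])
  }
  p_metal <- at$is_metal[pi]
  pair_rule(at$hydrophobic[pi], at$hydrophobic[li], params$d_hphob,
            "hydrophobic")
  pair_rule(at$donor[pi] & !p_metal, at$acceptor[li], params$d_hbond,
            "hbond_donor")
  pair_rule(at$acceptor[pi] & !p_metal, at$donor[li], params$d_hbond,
            "hbond_acceptor")
  pair_rule(at$charge[pi] == "+" & !p_metal, at$charge[li] == "-",
            params$d_salt, "salt_positive")
  pair_rule(at$charge[pi] == "-", at$charge[li] == "+", params$d_salt,
            "salt_negative")
  pair_rule(p_metal, at$charge[li] == "-" | at$acceptor[li], params$d_metal,
            "metal")

  prings <- Filter(function(r) !r$is_ligand, structure$rings)
  lrings <- Filter(function(r) r$is_ligand, structure$rings)
  for (pr in prings) for (lr in lrings) {
    dc <- vec_norm(pr$centroid - lr$centroid)
    if (dc > params$d_ring) next
    ang <- interplanar_angle(pr$normal, lr$normal)
    if (ang <= params$a_parallel)
      emit("aromatic_f2f", pr$members, lr$members, dc)
    else if (ang >= params$a_perp_lo && ang <= params$a_perp_hi)
      emit("aromatic_e2f", pr$members, lr$members, dc)
  }
  if (!length(out)) return(empty_contacts())
  do.call(rbind, out)
}

empty_contacts <- function() {
  data.frame(type = character(0), protein_res = character(0),
             protein_atoms = character(0), ligand_atoms = character(0),
             distance = numeric(0), stringsAsFactors = FALSE)
}

## shared builder for the two fingerprint resolutions
build_ifp <- function(structure, params, mode) {
  contacts <- detect_interactions(structure, params)
  types <- names(interaction_types())
  if (mode == "residue") {
    sites <- contacts$protein_res
  } else {
    ## one site per participating protein atom (aromatic contacts list all
    ## ring members, so the residue bit is the OR of its atomic bits)
    sites <- character(0)
    expand <- list()
    if (nrow(contacts)) for (k in seq_len(nrow(contacts))) {
      atom_names <- strsplit(contacts$protein_atoms[k], ",")[[1]]
      expand[[k]] <- data.frame(
        site = paste0(contacts$protein_res[k], ":", atom_names),
        type = contacts$type[k], stringsAsFactors = FALSE)
    }
    ec <- if (length(expand)) do.call(rbind, expand) else
      data.frame(site = character(0), type = character(0))
    contacts <- ec
    sites <- ec$site
  }
  usites <- sort(unique(sites))
  bits <- matrix(0L, length(usites), length(types),
                 dimnames = list(usites, types))
  if (nrow(contacts))
    bits[cbind(match(sites, usites), match(contacts$type, types))] <- 1L
  structure(list(target_id = structure$target_id,
                 fragment_id = structure$fragment_id,
                 mode = mode, sites = usites, bits = bits),
            class = "interaction_fingerprint")
}

#' Residue-level interaction fingerprint
#'
#' Binary fingerprint with one row per protein residue and one column per
#' interaction type; bit (r, t) is set iff some contact of type t involves
#' an atom of residue r (OR semantics over the residue's atoms).
#'
#' @inheritParams detect_interactions
#' @return An `"interaction_fingerprint"` (fields `mode`, `sites`, `bits`,
#'   `target_id`, `fragment_id`).
#' @export
residue_ifp <- function(structure, params = geometry_params()) {
  build_ifp(structure, params, "residue")
}

#' Atom-level interaction fingerprint
#'
#' As [residue_ifp()] but with one row per protein atom
#' (`"chain:resname:number:atomname"` sites); for aromatic stacking every
#' ring-member atom carries the bit, so collapsing atomic bits by residue
#' reproduces the residue fingerprint exactly.
#'
#' @inheritParams detect_interactions
#' @return An `"interaction_fingerprint"`.
#' @export
atomic_ifp <- function(structure, params = geometry_params()) {
  build_ifp(structure, params, "atomic")
}

#' Interaction keys of a fingerprint
#'
#' Renders the set bits as hashable key strings
#' `"target|site|type"`, the atomic unit of functional information.
#'
#' @param fp an `"interaction_fingerprint"`.
#' @return Character vector of keys (possibly empty).
#' @export
ifp_keys <- function(fp) {
  stopifnot(inherits(fp, "interaction_fingerprint"))
  hit <- which(fp$bits == 1L, arr.ind = TRUE)
  if (!nrow(hit)) return(character(0))
  sort(paste(fp$target_id, fp$sites[hit[, 1]],
             colnames(fp$bits)[hit[, 2]], sep = "|"))
}

#' Collapse an atomic fingerprint to residue resolution
#'
#' @param fp an atomic-mode `"interaction_fingerprint"`.
#' @return A residue-mode fingerprint whose bit (r, t) is the OR over the
#'   residue's atomic bits.
#' @export
collapse_to_residue <- function(fp) {
  stopifnot(inherits(fp, "interaction_fingerprint"), fp$mode == "atomic")
  res <- sub(":[^:]*$", "", fp$sites)
  ures <- sort(unique(res))
  bits <- matrix(0L, length(ures), ncol(fp$bits),
                 dimnames = list(ures, colnames(fp$bits)))
  for (i in seq_along(fp$sites))
    bits[res[i], ] <- bits[res[i], ] | fp$bits[i, ]
  mode(bits) <- "integer"
  structure(list(target_id = fp$target_id, fragment_id = fp$fragment_id,
                 mode = "residue", sites = ures, bits = bits),
            class = "interaction_fingerprint")
}

#' Tanimoto similarity of two interaction fingerprints
#'
#' Set-based Tanimoto over the on-bits, with site spaces aligned by site
#' id: `|intersection| / |union|`. Two all-zero fingerprints have
#' similarity 0 by convention.
#'
#' @param fp_a,fp_b fingerprints of the same mode for the same target
#'   (cross-target similarity is undefined).
#' @return Numeric in `[0, 1]`.
#' @export
ifp_tanimoto <- function(fp_a, fp_b) {
  stopifnot(inherits(fp_a, "interaction_fingerprint"),
            inherits(fp_b, "interaction_fingerprint"))
  if (fp_a$mode != fp_b$mode)
    stop("fingerprints have different modes")
  if (fp_a$target_id != fp_b$target_id)
    stop("cross-target IFP similarity is undefined")
  a <- ifp_keys(fp_a); b <- ifp_keys(fp_b)
  key_tanimoto(a, b)
}

## Tanimoto on key/bit-index sets; both empty -> 0
key_tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Write a fingerprint as TSV
#'
#' @param fp an `"interaction_fingerprint"`.
#' @param path output path.
#' @return `path`, invisibly. Columns `site`, `type`, `bit` (set bits only).
#' @export
write_ifp_tsv <- function(fp, path) {
  hit <- which(fp$bits == 1L, arr.ind = TRUE)
  df <- data.frame(site = fp$sites[hit[, 1]],
                   type = colnames(fp$bits)[hit[, 2]], bit = 1L)
  df <- df[order(df$site, df$type), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
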