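#' The eight supported protein-ligand interaction types
#'
#' Stable names and integer codes (0-7) for the eight interaction types the
#' fingerprint engine can detect: hydrophobic contact, aromatic face-to-face
#' and edge-to-face stacking, hydrogen bonds with the protein as donor or as
#' acceptor, salt bridges with the protein carrying the positive or the
#' negative charge, and ionic coordination to a protein-side metal.
#'
#' @return Named integer vector of length 8; names are the type labels used
#'   in interaction keys, values are the stable codes 0-7.
#' @export
#' @examples
#' interaction_types()
interaction_types <- function() {
  c(hydrophobic    = 0L,
    aromatic_f2f   = 1L,
    aromatic_e2f   = 2L,
    hbond_donor    = 3L,   # protein is the H-bond donor
    hbond_acceptor = 4L,   # protein is the H-bond acceptor
    salt_positive  = 5L,   # protein carries the positive charge
    salt_negative  = 6L,   # protein carries the negative charge
    metal          = 7L)   # ionic coordination to a protein-side metal
}

#' Geometric cutoffs for interaction detection
#'
#' Creates the parameter set used by [detect_interactions()]. Detection is
#' heavy-atom based (crystallographic fragment-screen models typically carry
#' no hydrogens), so hydrogen-bond and salt-bridge criteria are
#' donor/acceptor heavy-atom distances. All cutoffs are overridable here or
#' via a YAML file ([read_geometry_params()]).
#'
#' @param d_hphob hydrophobic heavy-atom contact cutoff, Angstrom.
#' @param d_hbond H-bond donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param d_salt salt-bridge distance cutoff between oppositely charged
#'   groups, Angstrom.
#' @param d_metal metal-to-ligand acceptor/anion coordination cutoff,
#'   Angstrom.
#' @param d_ring aromatic ring centroid-centroid cutoff, Angstrom.
#' @param a_parallel maximum interplanar angle (degrees) for face-to-face
#'   stacking.
#' @param a_perp_lo,a_perp_hi interplanar angle band (degrees) for
#'   edge-to-face stacking.
#' @return A list of class `"geometry_params"`.
#' @export
#' @examples
#' p <- geometry_params(d_hbond = 3.2)
#' p$d_hbond
geometry_params <- function(d_hphob = 4.0, d_hbond = 3.5, d_salt = 4.0,
                            d_metal = 3.0, d_ring = 5.0, a_parallel = 30,
                            a_perp_lo = 60, a_perp_hi = 120) {
  p <- list(d_hphob = d_hphob, d_hbond = d_hbond, d_salt = d_salt,
            d_metal = d_metal, d_ring = d_ring, a_parallel = a_parallel,
            a_perp_lo = a_perp_lo, a_perp_hi = a_perp_hi)
  stopifnot(all(vapply(p, is.numeric, logical(1))),
            all(unlist(p[1:5]) > 0),
            a_perp_lo < a_perp_hi)
  structure(p, class = "geometry_params")
}

#' Read geometry parameters from a YAML file
#'
#' Unspecified keys keep their [geometry_params()] defaults; unknown keys are
#' an error so typos in a config cannot silently loosen a cutoff.
#'
#' @param path path to a YAML file whose keys are `geometry_params()`
#'   arguments.
#' @return A `"geometry_params"` object.
#' @export
read_geometry_params <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(geometry_params))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown geometry parameter(s): ", paste(bad, collapse = ", "))
  do.call(geometry_params, vals)
}

#' Write geometry parameters to a YAML file
#'
#' @param params a `"geometry_params"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometry_params <- function(params, path) {
  stopifnot(inherits(params, "geometry_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

## ---- small vector helpers (shared by ifp and synthetic) ----

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) v / vec_norm(v)

## angle between two plane normals, folded to [0, 90] degrees
interplanar_angle <- function(n1, n2) {
  ct <- abs(sum(unit(n1) * unit(n2)))
  acos(pmin(1, ct)) * 180 / pi
}

## least-squares plane through points (n x 3): returns centroid + unit normal
ls_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = unit(sv$v[, 3]),
       rms = sqrt(mean((sweep(xyz, 2, ctr) %*% sv$v[, 3])^2)))
}

## rotation matrix about unit axis by angle (degrees), Rodrigues form
rotation_matrix <- function(axis, angle_deg) {
  a <- unit(axis); th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
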