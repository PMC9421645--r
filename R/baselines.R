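## Comparison orderings and molecular-fingerprint machinery: random
## shuffles, MACCS + MaxMin structurally diverse selections, and the
## pairwise structural-vs-functional similarity analysis.

#' Molecular fingerprints from SMILES
#'
#' Computes MACCS keys or ECFP2 (circular, radius 1 / diameter 2)
#' fingerprints via OpenBabel (ChemmineOB). Deterministic given canonical
#' SMILES.
#'
#' @param smiles named character vector of SMILES (names = fragment ids).
#' @param kind `"MACCS"` or `"ECFP2"`.
#' @return Named list of sorted on-bit index vectors with attribute
#'   `kind`; unparseable SMILES yield `NULL` entries with a message.
#' @export
molecular_fingerprints <- function(smiles, kind = c("MACCS", "ECFP2")) {
  kind <- match.arg(kind)
  ids <- names(smiles)
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  out <- stats::setNames(vector("list", length(smiles)), ids)
  for (i in seq_along(smiles)) {
    bits <- try(suppressWarnings({
      m <- ChemmineOB::forEachMol("SMILES", smiles[[i]], identity)
      fp <- ChemmineOB::fingerprint_OB(m, kind)
      if (is.matrix(fp)) fp <- fp[1, ]
      sort(which(fp != 0))
    }), silent = TRUE)
    if (inherits(bits, "try-error") || is.null(bits)) {
      message("unparseable SMILES for ", ids[i], "; skipped")
      next
    }
    out[[i]] <- as.integer(bits)
  }
  attr(out, "kind") <- kind
  out
}

#' Tanimoto similarity of two molecular fingerprints
#'
#' `|A intersect B| / |A union B|` over on-bit sets; two empty fingerprints
#' have similarity 0 by convention.
#'
#' @param a,b on-bit index vectors of the same fingerprint kind (as
#'   produced by [molecular_fingerprints()]).
#' @param kind_a,kind_b optional kind labels; a mismatch is an error.
#' @return Numeric in `[0, 1]`.
#' @export
tanimoto <- function(a, b, kind_a = NULL, kind_b = NULL) {
  if (!is.null(kind_a) && !is.null(kind_b) && kind_a != kind_b)
    stop("fingerprint kind mismatch: ", kind_a, " vs ", kind_b)
  key_tanimoto(a, b)
}

#' Random fragment orderings
#'
#' Uniform permutations, the standard random control; run r uses seed
#' `seed + r - 1`.
#'
#' @param fragment_ids character vector to order.
#' @param n_runs number of shuffles.
#' @param seed master seed.
#' @return List of orderings (character vectors).
#' @export
random_order <- function(fragment_ids, n_runs = 100L, seed = 0L) {
  stopifnot(length(fragment_ids) >= 1)
  lapply(seq_len(n_runs), function(r) {
    set.seed(seed + r - 1L)
    sample(fragment_ids)
  })
}

#' MaxMin structurally diverse orderings
#'
#' The conventional diversity baseline: a uniform-random initial pick per
#' run, then each subsequent pick maximizes the minimum Tanimoto distance
#' (1 - similarity) to the already-picked set. The full ordering is
#' returned, so every k-prefix is the size-k diverse selection with that
#' initial pick.
#'
#' @param fps named list of fingerprints (see [molecular_fingerprints()]).
#' @param n_runs number of repetitions (initial pick varies).
#' @param seed master seed; run r uses `seed + r - 1`.
#' @return List of orderings (names of `fps`).
#' @export
maxmin_order <- function(fps, n_runs = 100L, seed = 0L) {
  n <- length(fps)
  stopifnot(n >= 2, !is.null(names(fps)))
  ## pairwise distance matrix 1 - Tanimoto
  D <- matrix(0, n, n, dimnames = list(names(fps), names(fps)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- 1 - key_tanimoto(fps[[i]], fps[[j]])
  lapply(seq_len(n_runs), function(r) {
    set.seed(seed + r - 1L)
    picked <- sample.int(n, 1)
    remaining <- setdiff(seq_len(n), picked)
    mind <- D[, picked]
    while (length(remaining)) {
      nxt <- remaining[which.max(mind[remaining])]
      picked <- c(picked, nxt)
      remaining <- setdiff(remaining, nxt)
      mind <- pmin(mind, D[, nxt])
    }
    names(fps)[picked]
  })
}

#' Structural vs functional pairwise similarity analysis
#'
#' For every unordered pair of bound fragments and every target both have
#' bound, records the molecular (ECFP2) similarity, the interaction
#' fingerprint similarity on that target, the number of shared interaction
#' keys, and whether the two profiles are identical (the signature of
#' structurally distinct but functionally equivalent fragments).
#'
#' @param dataset a `"screen_dataset"` whose fragments carry SMILES
#'   (ECFP2 similarities are `NA` otherwise).
#' @param mode fingerprint resolution for the functional similarity.
#' @param denominator `"bound"` (default) or `"all"`: the fragment-pair
#'   universe used for the summary fractions.
#' @return List with `records` (data frame `frag_a,frag_b,target,ecfp2_sim,
#'   ifp_sim,shared,identical`) and `summary` (`identical_pairs`,
#'   `identical_fraction`, `shared_ge1_fraction`, `n_pairs`).
#' @export
pair_analysis <- function(dataset, mode = c("residue", "atomic"),
                          denominator = c("bound", "all")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  stopifnot(inherits(dataset, "screen_dataset"))
  prof <- dataset$profiles[[mode]]
  fid <- dataset$fragments$fragment_id
  bound <- fid[dataset$fragments$n_bound > 0]
  smiles <- NULL
  if ("smiles" %in% names(dataset$fragments))
    smiles <- stats::setNames(dataset$fragments$smiles, fid)
  efp <- NULL
  if (!is.null(smiles) && any(!is.na(smiles[bound])))
    efp <- molecular_fingerprints(smiles[bound], "ECFP2")

  key_target <- function(k) sub("\\|.*$", "", k)
  by_target <- lapply(prof[bound], function(k)
    split(k, key_target(k)))

  rec <- list()
  n <- length(bound)
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    a <- bound[i]; b <- bound[j]
    common <- intersect(names(by_target[[a]]), names(by_target[[b]]))
    if (!length(common)) next
    es <- NA_real_
    if (!is.null(efp) && !is.null(efp[[a]]) && !is.null(efp[[b]]))
      es <- key_tanimoto(efp[[a]], efp[[b]])
    for (t in common) {
      ka <- by_target[[a]][[t]]; kb <- by_target[[b]][[t]]
      sim <- key_tanimoto(ka, kb)
      rec[[length(rec) + 1]] <- data.frame(
        frag_a = a, frag_b = b, target = t, ecfp2_sim = es,
        ifp_sim = sim, shared = length(intersect(ka, kb)),
        identical = sim == 1 && length(ka) > 0,
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(frag_a = character(0), frag_b = character(0),
               target = character(0), ecfp2_sim = numeric(0),
               ifp_sim = numeric(0), shared = integer(0),
               identical = logical(0))

  pool <- if (denominator == "bound") bound else fid
  n_pairs <- choose(length(pool), 2)
  pair_id <- paste(records$frag_a, records$frag_b)
  identical_pairs <- length(unique(pair_id[records$identical]))
  shared_pairs <- length(unique(pair_id[records$shared >= 1]))
  list(records = records,
       summary = list(
         identical_pairs = identical_pairs,
         identical_fraction = if (n_pairs) identical_pairs / n_pairs else 0,
         shared_ge1_fraction = if (n_pairs) shared_pairs / n_pairs else 0,
         n_pairs = n_pairs))
}

#' Overlap between two library prefixes
#'
#' @param order_a,order_b fragment orderings.
#' @param k prefix size (must not exceed either length).
#' @return Number of fragments in common between the two size-k libraries.
#' @export
library_overlap <- function(order_a, order_b, k) {
  stopifnot(k <= length(order_a), k <= length(order_b))
  length(intersect(order_a[seq_len(k)], order_b[seq_len(k)]))
}
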