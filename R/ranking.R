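## Greedy functional-diversity ranking: fragments are appended one by one,
## each time taking the fragment that adds the largest number of novel
## interaction keys to the growing library. Ties are broken by position in
## a per-run random shuffle of the candidate list, the protocol's stated
## source of run-to-run variability.

## profiles of a dataset restricted to a target subset
restrict_profiles <- function(dataset, targets = NULL,
                              mode = c("residue", "atomic")) {
  mode <- match.arg(mode)
  prof <- dataset$profiles[[mode]]
  if (is.null(targets)) return(prof)
  lapply(prof, function(k) {
    if (!length(k)) return(character(0))
    k[sub("\\|.*$", "", k) %in% targets]
  })
}

#' The interaction universe of a profile set
#'
#' @param profiles named list of interaction-key vectors.
#' @return Sorted character vector of unique keys.
#' @export
interaction_universe <- function(profiles) {
  sort(unique(unlist(profiles, use.names = FALSE)))
}

#' Greedy functional-diversity ranking
#'
#' Ranks fragments by the novel interaction keys they contribute. Each run
#' shuffles the candidate list with a run-specific seed (`seed + run - 1`),
#' then iteratively selects the fragment with maximal marginal gain, ties
#' going to the earliest fragment in the shuffled list. Fragments whose
#' remaining gain is zero are appended after all positive-gain fragments in
#' shuffled order, so the full bound set is always ranked. Never-bound
#' fragments (no interaction key on the ranked targets) are excluded.
#'
#' @param dataset a `"screen_dataset"`.
#' @param targets ranking target subset (default: all targets).
#' @param mode `"residue"` or `"atomic"` fingerprint resolution.
#' @param n_runs number of shuffled repetitions.
#' @param seed master seed; run r uses `seed + r - 1`.
#' @return List of `"ranking_run"` objects, each with `seed`, `order`
#'   (fragment ids), `marginal_gain` (novel keys contributed at each
#'   position), `mode`, `targets` and `universe_size`.
#' @export
greedy_rank <- function(dataset, targets = NULL,
                        mode = c("residue", "atomic"),
                        n_runs = 100L, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "screen_dataset"), n_runs >= 1)
  if (is.null(targets)) targets <- dataset$targets
  prof <- restrict_profiles(dataset, targets, mode)
  universe <- interaction_universe(prof)
  if (!length(universe)) stop("no interactions to rank")
  pool <- names(prof)[vapply(prof, length, integer(1)) > 0]
  M <- matrix(0L, length(pool), length(universe),
              dimnames = list(pool, universe))
  for (f in pool) M[f, prof[[f]]] <- 1L

  lapply(seq_len(n_runs), function(r) {
    run_seed <- seed + r - 1L
    set.seed(run_seed)
    shuf <- sample(pool)
    Ms <- M[shuf, , drop = FALSE]
    n <- length(shuf)
    uncov <- rep(1, length(universe))
    remaining <- rep(TRUE, n)
    ord <- character(n); gain <- integer(n)
    for (pos in seq_len(n)) {
      gains <- as.vector(Ms %*% uncov)
      gains[!remaining] <- -1
      best <- which.max(gains)
      g <- gains[best]
      if (g <= 0) {
        ## zero-gain tail keeps shuffled relative order
        tail_idx <- which(remaining)
        ord[pos:n] <- shuf[tail_idx]
        gain[pos:n] <- 0L
        break
      }
      ord[pos] <- shuf[best]
      gain[pos] <- as.integer(g)
      uncov[Ms[best, ] == 1L] <- 0
      remaining[best] <- FALSE
    }
    structure(list(seed = run_seed, order = ord, marginal_gain = gain,
                   mode = mode, targets = targets,
                   universe_size = length(universe)),
              class = "ranking_run")
  })
}

#' Information-recovery curve over repeated orderings
#'
#' For each library size k, the fraction of the interaction universe covered
#' by the union of the first k fragments' profiles; mean and standard
#' deviation taken across runs. Orderings shorter than `max_size` are
#' padded with zero-information dummy fragments, so the curve is constant
#' beyond the last ranked fragment.
#'
#' @param orderings list of fragment-id vectors (e.g. `$order` of
#'   [greedy_rank()] runs, or baseline orderings).
#' @param universe the interaction keys to recover.
#' @param profiles named list of interaction-key vectors.
#' @param max_size evaluate sizes `1..max_size` (default: longest ordering).
#' @return A `"recovery_curve"`: data frame with `size`, `mean_fraction`,
#'   `std_fraction`, plus attributes `n_runs` and `universe_size`.
#' @export
recovery_curve <- function(orderings, universe, profiles, max_size = NULL) {
  if (inherits(orderings, "ranking_run")) orderings <- list(orderings)
  orderings <- lapply(orderings, function(o)
    if (inherits(o, "ranking_run")) o$order else o)
  stopifnot(length(orderings) >= 1)
  if (!length(universe)) stop("empty interaction universe")
  if (is.null(max_size))
    max_size <- max(vapply(orderings, length, integer(1)))
  frac <- vapply(orderings, function(ord) {
    kf <- integer(max_size)
    covered <- logical(length(universe))
    n <- min(length(ord), max_size)
    for (k in seq_len(n)) {
      keys <- profiles[[ord[k]]]
      if (length(keys)) {
        idx <- match(keys, universe)
        covered[idx[!is.na(idx)]] <- TRUE
      }
      kf[k] <- sum(covered)
    }
    if (n < max_size) kf[(n + 1):max_size] <- kf[n]
    kf / length(universe)
  }, numeric(max_size))
  frac <- matrix(frac, nrow = max_size)
  std <- apply(frac, 1, stats::sd)
  std[is.na(std)] <- 0
  structure(data.frame(size = seq_len(max_size),
                       mean_fraction = rowMeans(frac),
                       std_fraction = std),
            n_runs = length(orderings), universe_size = length(universe),
            class = c("recovery_curve", "data.frame"))
}

#' Greedy minimum cover size of a ranking run
#'
#' The smallest library size at which the run's cumulative gain equals the
#' interaction universe, i.e. the number of fragments the greedy protocol
#' needs to recover every interaction (the greedy cover, not the NP-hard
#' optimum).
#'
#' @param run a `"ranking_run"`.
#' @return Integer library size.
#' @export
minimum_cover_size <- function(run) {
  stopifnot(inherits(run, "ranking_run"))
  cum <- cumsum(run$marginal_gain)
  k <- which(cum >= run$universe_size)
  if (!length(k)) stop("run does not cover its universe")
  as.integer(k[1])
}

#' Assign fragments to ranking groups
#'
#' Partitions the full fragment set given one ranking run: the first
#' `top_n` ranked fragments (`TOP_100`), ranked fragments beyond `top_n`
#' but inside the greedy minimum cover with positive marginal gain
#' (`REMAINING_MINIMUM`), bound fragments that contributed no novel
#' interaction when selected (`REDUNDANT`), other bound fragments outside
#' the minimum cover (`REMAINING_BOUND`), and fragments never observed to
#' bind (`NEVER_BOUND`).
#'
#' @param dataset a `"screen_dataset"`.
#' @param run a `"ranking_run"` covering the dataset's bound fragments.
#' @param top_n size of the top group (default 100).
#' @return Named character vector (fragment id -> group); the groups always
#'   partition the fragment set.
#' @export
assign_groups <- function(dataset, run, top_n = 100L) {
  stopifnot(inherits(dataset, "screen_dataset"),
            inherits(run, "ranking_run"))
  fid <- dataset$fragments$fragment_id
  groups <- stats::setNames(rep("NEVER_BOUND", length(fid)), fid)
  bound <- fid[dataset$fragments$n_bound > 0]
  groups[bound] <- "REMAINING_BOUND"
  ord <- run$order
  if (top_n > length(ord)) {
    warning("top_n (", top_n, ") exceeds ranked fragment count (",
            length(ord), "); top group truncated")
    top_n <- length(ord)
  }
  cover <- minimum_cover_size(run)
  pos <- seq_along(ord)
  groups[ord[run$marginal_gain == 0L]] <- "REDUNDANT"
  groups[ord[pos > top_n & pos <= cover & run$marginal_gain > 0L]] <-
    "REMAINING_MINIMUM"
  groups[ord[pos <= top_n]] <- "TOP_100"
  groups
}
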