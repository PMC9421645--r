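## Leave-one-out unseen-target evaluation: rank fragments on every target
## except one, measure how fast the held-out target's interactions are
## recovered, and compare the functional ranking against random and
## structurally diverse baselines. Pairwise target impact scores quantify
## how much one training target helps another.

#' Leave-one-out unseen-target recovery
#'
#' Ignores the held-out target's screen entirely for ranking: fragments are
#' ordered using only the remaining targets' interaction profiles
#' (functional greedy ranking, random shuffles, or MACCS + MaxMin
#' structural diversity over the same rankable pool), then recovery is
#' measured against the held-out target's interaction universe. Past the
#' last rankable fragment, zero-information dummy fragments extend every
#' curve to `max_size`.
#'
#' @param dataset a `"screen_dataset"`.
#' @param held_out target id to hold out.
#' @param method `"functional"`, `"random"` or `"structural"`.
#' @param mode fingerprint resolution.
#' @param max_size curve length (library sizes 1..max_size; default 200).
#' @param n_runs repetitions.
#' @param seed master seed.
#' @return A `"loo_result"`: list with `held_out`, `method`, `mode`,
#'   `curve` (a [recovery_curve()] over the held-out universe),
#'   `pool_size` (rankable fragments).
#' @export
leave_one_out <- function(dataset, held_out,
                          method = c("functional", "random", "structural"),
                          mode = c("residue", "atomic"),
                          max_size = 200L, n_runs = 100L, seed = 0L) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "screen_dataset"),
            held_out %in% dataset$targets,
            length(dataset$targets) >= 2)
  training <- setdiff(dataset$targets, held_out)
  train_prof <- restrict_profiles(dataset, training, mode)
  pool <- names(train_prof)[vapply(train_prof, length, integer(1)) > 0]
  if (!length(pool)) stop("no rankable fragments on the training targets")
  held_prof <- restrict_profiles(dataset, held_out, mode)
  held_universe <- interaction_universe(held_prof)
  if (!length(held_universe))
    stop("held-out target ", held_out, " has an empty interaction universe")

  orderings <- switch(method,
    functional = lapply(greedy_rank(dataset, training, mode,
                                    n_runs = n_runs, seed = seed),
                        `[[`, "order"),
    random = random_order(pool, n_runs = n_runs, seed = seed),
    structural = {
      if (!("smiles" %in% names(dataset$fragments)))
        stop("structural baseline requires fragment SMILES")
      smiles <- stats::setNames(dataset$fragments$smiles,
                                dataset$fragments$fragment_id)[pool]
      fps <- molecular_fingerprints(smiles, "MACCS")
      fps <- fps[!vapply(fps, is.null, logical(1))]
      maxmin_order(fps, n_runs = n_runs, seed = seed)
    })
  curve <- recovery_curve(orderings, held_universe, held_prof,
                          max_size = max_size)
  structure(list(held_out = held_out, method = method, mode = mode,
                 curve = curve, pool_size = length(pool)),
            class = "loo_result")
}

#' Mean recovery at a given library size
#'
#' @param result a `"loo_result"` (or anything with a `curve` recovery
#'   curve).
#' @param k library size; `k = 0` returns 0.
#' @return Mean recovered fraction of the held-out universe at size k.
#' @export
recovery_at_size <- function(result, k) {
  curve <- if (inherits(result, "recovery_curve")) result else result$curve
  stopifnot(k >= 0, k <= nrow(curve))
  if (k == 0) return(0)
  curve$mean_fraction[k]
}

#' Fractional improvement of the functional ranking over a baseline
#'
#' `100 * (functional - baseline) / baseline` at library size k, both
#' evaluated on the same held-out target (ratio of mean recoveries).
#'
#' @param functional,baseline `"loo_result"` objects for the same held-out
#'   target.
#' @param k library size (default 100).
#' @return Percentage (numeric). When the baseline recovery is zero and the
#'   functional recovery positive, `Inf` with attribute
#'   `infinite_baseline = TRUE`.
#' @export
fractional_improvement <- function(functional, baseline, k = 100L) {
  stopifnot(functional$held_out == baseline$held_out)
  f <- recovery_at_size(functional, k)
  b <- recovery_at_size(baseline, k)
  if (b == 0) {
    if (f == 0) return(0)
    out <- Inf
    attr(out, "infinite_baseline") <- TRUE
    return(out)
  }
  100 * (f - b) / b
}

#' Pairwise target impact matrix
#'
#' For every ordered target pair (i, j), i != j: hold out j, rank the
#' fragments on the remaining targets with and without i, and report the
#' percentage change in mean recovery of j's interactions at library size
#' k. Positive entries mean that screening i makes the library more
#' informative about j.
#'
#' @param dataset a `"screen_dataset"` with at least 3 targets.
#' @param k library size at which recovery is compared (default 100).
#' @param mode fingerprint resolution.
#' @param n_runs repetitions per ranking configuration.
#' @param seed master seed (shared across configurations).
#' @param relative percentage change (default) or absolute difference in
#'   recovered fraction when `FALSE`.
#' @return An `"impact_matrix"`: square numeric matrix (rows = included
#'   training target i, columns = evaluated target j), diagonal `NA`;
#'   entries with zero baseline recovery are `NA` and listed in attribute
#'   `flagged`.
#' @export
impact_matrix <- function(dataset, k = 100L, mode = c("residue", "atomic"),
                          n_runs = 100L, seed = 0L, relative = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "screen_dataset"),
            length(dataset$targets) >= 3)
  tg <- dataset$targets
  m <- matrix(NA_real_, length(tg), length(tg), dimnames = list(tg, tg))
  flagged <- character(0)

  mean_recovery <- function(ranking_targets, held) {
    held_prof <- restrict_profiles(dataset, held, mode)
    held_universe <- interaction_universe(held_prof)
    if (!length(held_universe)) return(NA_real_)
    runs <- greedy_rank(dataset, ranking_targets, mode,
                        n_runs = n_runs, seed = seed)
    curve <- recovery_curve(lapply(runs, `[[`, "order"), held_universe,
                            held_prof, max_size = k)
    curve$mean_fraction[k]
  }

  for (j in tg) {
    training <- setdiff(tg, j)
    r_with <- mean_recovery(training, j)
    for (i in training) {
      r_without <- mean_recovery(setdiff(training, i), j)
      if (is.na(r_with) || is.na(r_without)) next
      if (relative) {
        if (r_without == 0) {
          flagged <- c(flagged, paste(i, j, sep = "->"))
          next
        }
        m[i, j] <- 100 * (r_with - r_without) / r_without
      } else {
        m[i, j] <- r_with - r_without
      }
    }
  }
  structure(m, k = k, mode = mode, n_runs = n_runs, flagged = flagged,
            class = c("impact_matrix", "matrix"))
}

#' Physicochemical property profile by fragment group
#'
#' Computes standard fragment descriptors (molecular weight, heavy-atom
#' count, H-bond donors and acceptors, rotatable bonds, cLogP) per
#' fragment, tabulates them into configurable bins per group, and collects
#' the intra-group pairwise MACCS similarity distributions.
#'
#' @param fragments data frame with `fragment_id` and `smiles`.
#' @param groups named vector fragment id -> group (see [assign_groups()]).
#' @param bins named list of numeric bin edges per descriptor; defaults
#'   cover typical fragment ranges.
#' @return List with `descriptors` (per-fragment data frame including
#'   `group`), `binned` (per-descriptor count tables, group x bin),
#'   `maccs_similarity` (per-group numeric vectors of pairwise Tanimoto),
#'   and `group_sizes`. Unparseable SMILES are skipped with a message.
#' @export
property_profile <- function(fragments, groups, bins = NULL) {
  stopifnot(all(c("fragment_id", "smiles") %in% names(fragments)))
  if (is.null(bins))
    bins <- list(MW = c(0, 100, 150, 175, 200, 240, 300, Inf),
                 heavy_atoms = c(0, 8, 12, 16, 20, Inf),
                 HBD = c(-0.5, 0.5, 1.5, 2.5, Inf),
                 HBA = c(-0.5, 1.5, 3.5, 5.5, Inf),
                 rot_bonds = c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf),
                 cLogP = c(-Inf, 0, 1, 2, 3, Inf))
  desc <- list()
  for (i in seq_len(nrow(fragments))) {
    fid <- fragments$fragment_id[i]
    smi <- fragments$smiles[i]
    row <- try(suppressWarnings({
      sdf <- ChemmineR::smiles2sdf(stats::setNames(smi, fid))
      pr <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smi,
                                                       identity))
      ab <- ChemmineR::atomblock(sdf[[1]])
      heavy <- sum(!grepl("^H_", rownames(ab)))
      rot <- ChemmineOB::smartsSearch_OB(
        ChemmineOB::forEachMol("SMILES", smi, identity),
        "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", uniqueMatches = TRUE)
      data.frame(fragment_id = fid, MW = pr$MW, heavy_atoms = heavy,
                 HBD = pr$HBD, HBA = pr$HBA1 + pr$HBA2, rot_bonds = rot,
                 cLogP = pr$logP, stringsAsFactors = FALSE)
    }), silent = TRUE)
    if (inherits(row, "try-error")) {
      message("unparseable SMILES for ", fid, "; skipped")
      next
    }
    desc[[length(desc) + 1]] <- row
  }
  descriptors <- do.call(rbind, desc)
  descriptors$group <- unname(groups[descriptors$fragment_id])

  binned <- lapply(names(bins), function(p) {
    cut_p <- cut(descriptors[[p]], breaks = bins[[p]],
                 include.lowest = TRUE)
    table(group = descriptors$group, bin = cut_p)
  })
  names(binned) <- names(bins)

  smiles <- stats::setNames(fragments$smiles, fragments$fragment_id)
  sim_by_group <- lapply(split(descriptors$fragment_id, descriptors$group),
                         function(ids) {
    if (length(ids) < 2) return(numeric(0))
    fps <- molecular_fingerprints(smiles[ids], "MACCS")
    fps <- fps[!vapply(fps, is.null, logical(1))]
    n <- length(fps)
    if (n < 2) return(numeric(0))
    sims <- numeric(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      sims <- c(sims, key_tanimoto(fps[[i]], fps[[j]]))
    sims
  })
  list(descriptors = descriptors, binned = binned,
       maccs_similarity = sim_by_group,
       group_sizes = table(descriptors$group))
}
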