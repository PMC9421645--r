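test_that("the worked 4-fragment instance ranks as brute force dictates", {
  ds <- abcd_dataset()
  runs <- greedy_rank(ds, n_runs = 20, seed = 0)
  for (run in runs) {
    expect_equal(run$order[1], "A")            # unique argmax, gain 3
    expect_equal(run$marginal_gain[1], 3L)
    expect_equal(minimum_cover_size(run), 3L)  # A + {B,C} in either order
    expect_setequal(run$order[2:3], c("B", "C"))
    expect_equal(run$order[4], "D")            # fully redundant
    expect_equal(run$marginal_gain[4], 0L)
    expect_equal(sum(run$marginal_gain), run$universe_size)
  }
  curve <- recovery_curve(runs, interaction_universe(ds$profiles$residue),
                          ds$profiles$residue)
  expect_equal(curve$mean_fraction[3], 1)
  expect_equal(curve$std_fraction[3], 0)
})

test_that("group assignment on the worked instance", {
  ds <- abcd_dataset()
  run <- greedy_rank(ds, n_runs = 1, seed = 0)[[1]]
  groups <- assign_groups(ds, run, top_n = 2)
  expect_equal(unname(groups["A"]), "TOP_100")
  second <- run$order[2]
  third <- run$order[3]
  expect_equal(unname(groups[second]), "TOP_100")
  expect_equal(unname(groups[third]), "REMAINING_MINIMUM")
  expect_equal(unname(groups["D"]), "REDUNDANT")
})

test_that("disjoint singleton profiles recover linearly", {
  profs <- stats::setNames(lapply(1:4, tkeys), paste0("f", 1:4))
  ds <- make_profile_dataset(profs)
  runs <- greedy_rank(ds, n_runs = 3, seed = 1)
  expect_equal(minimum_cover_size(runs[[1]]), 4L)
  curve <- recovery_curve(runs, interaction_universe(profs), profs)
  expect_equal(curve$mean_fraction, c(0.25, 0.5, 0.75, 1))
  expect_equal(curve$std_fraction, rep(0, 4))
})

test_that("every greedy step selects a maximal marginal gain", {
  for (s in 1:60) {
    profiles <- rand_instance(seed = s)
    ds <- make_profile_dataset(lapply(profiles, tkeys))
    run <- greedy_rank(ds, n_runs = 1, seed = s)[[1]]
    covered <- character(0)
    remaining <- names(profiles)
    for (pos in seq_along(run$order)) {
      gains <- vapply(remaining, function(f)
        length(setdiff(tkeys(profiles[[f]]), covered)), integer(1))
      picked <- run$order[pos]
      expect_equal(length(setdiff(tkeys(profiles[[picked]]), covered)),
                   max(gains))
      covered <- union(covered, tkeys(profiles[[picked]]))
      remaining <- setdiff(remaining, picked)
    }
    expect_equal(length(covered), run$universe_size)
  }
})

test_that("greedy coverage is within (1 - 1/e) of the optimum at every k", {
  bound <- 1 - exp(-1)
  for (s in 1:15) {
    profiles <- rand_instance(seed = 500 + s, max_frags = 10, max_keys = 20)
    ds <- make_profile_dataset(lapply(profiles, tkeys))
    run <- greedy_rank(ds, n_runs = 1, seed = s)[[1]]
    masks <- lapply(profiles[run$order], bitmask)
    names(masks) <- NULL
    opt <- brute_max_coverage(lapply(profiles, bitmask))
    greedy_cov <- cumsum(run$marginal_gain)
    for (k in seq_along(opt))
      expect_gte(greedy_cov[k], bound * opt[k] - 1e-9)
  }
})

test_that("identical master seeds reproduce identical runs", {
  ds <- generate_binding_matrix(synthetic_spec(n_fragments = 60,
                                               n_targets = 4,
                                               seed = 3))$dataset
  r1 <- greedy_rank(ds, n_runs = 5, seed = 42)
  r2 <- greedy_rank(ds, n_runs = 5, seed = 42)
  expect_identical(r1, r2)
  r3 <- greedy_rank(ds, n_runs = 5, seed = 43)
  expect_false(identical(lapply(r1, `[[`, "order"),
                         lapply(r3, `[[`, "order")))
})

test_that("greedy recovery dominates random recovery in the mean", {
  gen <- generate_binding_matrix(synthetic_spec(n_fragments = 150,
                                                n_targets = 5,
                                                redundancy = 3, seed = 5))
  ds <- gen$dataset
  prof <- ds$profiles$residue
  universe <- interaction_universe(prof)
  pool <- names(prof)[vapply(prof, length, integer(1)) > 0]
  g <- recovery_curve(greedy_rank(ds, n_runs = 50, seed = 1),
                      universe, prof)
  r <- recovery_curve(random_order(pool, n_runs = 50, seed = 1),
                      universe, prof, max_size = nrow(g))
  expect_true(all(g$mean_fraction >= r$mean_fraction - 1e-12))
})

test_that("groups always partition the fragment set", {
  for (s in 1:30) {
    gen <- generate_binding_matrix(synthetic_spec(n_fragments = 40,
                                                  n_targets = 3, seed = s))
    ds <- gen$dataset
    if (!any(ds$fragments$n_bound > 0)) next
    run <- greedy_rank(ds, n_runs = 1, seed = s)[[1]]
    groups <- suppressWarnings(assign_groups(ds, run, top_n = 10))
    expect_setequal(names(groups), ds$fragments$fragment_id)
    expect_true(all(groups %in% c("TOP_100", "REMAINING_MINIMUM",
                                  "REMAINING_BOUND", "REDUNDANT",
                                  "NEVER_BOUND")))
    bound <- ds$fragments$fragment_id[ds$fragments$n_bound > 0]
    expect_setequal(names(groups)[groups == "NEVER_BOUND"],
                    setdiff(ds$fragments$fragment_id, bound))
  }
})

test_that("degenerate ranking inputs error cleanly", {
  ds <- make_profile_dataset(list(A = tkeys(1), B = character(0)))
  expect_error(greedy_rank(ds, targets = "T99"), "no interactions")
  expect_error(recovery_curve(list(c("A")), character(0),
                              ds$profiles$residue), "empty")
})

test_that("top_n beyond the ranked pool warns and truncates", {
  ds <- abcd_dataset()
  run <- greedy_rank(ds, n_runs = 1, seed = 0)[[1]]
  expect_warning(groups <- assign_groups(ds, run, top_n = 10), "truncated")
  expect_true(all(groups[c("A", "B", "C", "D")] == "TOP_100"))
})
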