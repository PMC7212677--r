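test_that("the 2016 screening volumes return exactly 3,650 new cases", {
  s <- poltava_screening_2016()
  total <- s$facility_screens + s$outreach_screens
  cases <- cases_identified(total, s$outreach_screens / total,
                            s$outreach_positivity, s$facility_positivity)
  expect_equal(cases, 3650)
  expect_equal(cases_identified(1e4, 0.5, 0, 0), 0)
  expect_equal(cases_identified(1e4, 1, 0.16, 0.08), 1600)
})

test_that("screens_for_target inverts cases_identified", {
  v <- screens_for_target(5000, 0, 0.0801, 0.08)
  expect_equal(v$facility_screens, 5000 / 0.0801)
  expect_equal(v$outreach_screens, 0)

  zero <- screens_for_target(0, 0.3, 0.08, 0.12)
  expect_equal(zero$total_screens, 0)
  expect_equal(zero$facility_screens, 0)

  set.seed(5)
  for (i in 1:50) {
    target <- runif(1, 1, 1e4)
    share <- runif(1)
    pf <- runif(1, 0.01, 0.3); po <- runif(1, 0.01, 0.3)
    v <- screens_for_target(target, share, pf, po)
    expect_equal(cases_identified(v$total_screens, share, po, pf), target,
                 tolerance = 1e-9)
  }
  expect_error(screens_for_target(100, 0.5, 0, 0), "infeasible")
})

test_that("scenario costs respect their closed forms and bounds", {
  crv <- cost_curve(0.66, 0.10, 1.4e6)
  all_fac <- scenario_cost(5000, 0, 0.0801, 0.08, 0.66, crv)
  expect_true(all_fac$feasible)
  expect_equal(all_fac$cost_per_case, 0.66 / 0.0801, tolerance = 1e-12)

  # outreach average cost >= unit cost, so every feasible scenario sits on
  # or above the blended linear lower bound
  set.seed(13)
  for (i in 1:50) {
    share <- runif(1); pf <- runif(1, 0.02, 0.2); po <- runif(1, 0.02, 0.2)
    sc <- scenario_cost(5000, share, pf, po, 0.66, crv)
    if (!sc$feasible) next
    blended <- (1 - share) * pf + share * po
    expect_gte(sc$cost_per_case, 0.66 / blended - 1e-9)
  }

  # implied coverage at/beyond saturation is infeasible
  tight <- cost_curve(0.66, 0.01, 1e4)
  sc <- scenario_cost(5000, 1, 0.08, 0.08, 0.66, tight)
  expect_false(sc$feasible)
})

test_that("optimize_share agrees with brute-force enumeration", {
  grid <- seq(0, 1, length.out = 41)
  set.seed(29)
  for (i in 1:10) {
    po <- runif(1, 0.08, 0.16)
    sat <- runif(1, 0.10, 0.20)
    res <- optimize_share(5000, po, sat, share_grid = grid)
    crv <- cost_curve(0.66, sat, 1.4e6)
    brute <- vapply(grid, function(s) {
      sc <- scenario_cost(5000, s, 3350 / 41833, po, 0.66, crv)
      if (sc$feasible) sc$cost_per_case else Inf
    }, numeric(1))
    expect_equal(res$min_cost_per_case, min(brute), tolerance = 1e-12)
    expect_equal(res$optimal_share, grid[which.min(brute)])
  }
})

test_that("degenerate share grids reduce to the facility-only scenario", {
  res <- optimize_share(5000, 0.12, 0.15, share_grid = 0)
  expect_equal(res$optimal_share, 0)
  expect_equal(res$min_cost_per_case, 0.66 / (3350 / 41833), tolerance = 1e-12)
})

test_that("better-targeted, more scalable outreach earns a larger optimal share", {
  lo <- optimize_share(5000, 0.08, 0.10)
  hi <- optimize_share(5000, 0.16, 0.20)
  expect_gte(hi$optimal_share, lo$optimal_share)
  expect_lte(hi$min_cost_per_case, lo$min_cost_per_case)
})

test_that("the grid sweep reproduces per-pair optima and the heatmap orderings", {
  g <- sweep_screening_grid(5000,
                            positivity_grid = seq(0.08, 0.16, length.out = 5),
                            saturation_grid = c(0.10, 0.15, 0.20),
                            share_grid = seq(0, 1, length.out = 51))
  # a 1x1x1 grid reduces to optimize_share
  single <- sweep_screening_grid(5000, positivity_grid = 0.12,
                                 saturation_grid = 0.15, share_grid = 0.2)
  direct <- optimize_share(5000, 0.12, 0.15, share_grid = 0.2)
  expect_equal(single$optima$min_cost_per_case, direct$min_cost_per_case)

  # per-pair minimum is <= every feasible grid value in its slice
  for (k in seq_len(nrow(g$optima))) {
    slice <- g$grid[g$grid$positivity == g$optima$positivity[k] &
                      g$grid$saturation == g$optima$saturation[k] &
                      g$grid$feasible, ]
    expect_true(all(g$optima$min_cost_per_case[k] <=
                      slice$cost_per_case + 1e-12))
  }

  # cost per case at the optimum is non-increasing in positivity and
  # saturation; the optimal share is non-decreasing in both
  o <- g$optima
  for (sat in unique(o$saturation)) {
    x <- o[o$saturation == sat, ]
    x <- x[order(x$positivity), ]
    expect_true(all(diff(x$min_cost_per_case) <= 1e-9))
    expect_true(all(diff(x$optimal_share) >= -1e-9))
  }
  for (p in unique(o$positivity)) {
    x <- o[o$positivity == p, ]
    x <- x[order(x$saturation), ]
    expect_true(all(diff(x$min_cost_per_case) <= 1e-9))
    expect_true(all(diff(x$optimal_share) >= -1e-9))
  }
})
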