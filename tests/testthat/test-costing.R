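test_that("unit costs apply VAT to drugs (7%) and consumables (20%) before conversion", {
  fx <- 26.3138
  expect_equal(build_unit_cost(cost_ingredients()), 0)
  expect_equal(build_unit_cost(cost_ingredients(drug_cost = 100), fx),
               107 / fx, tolerance = 1e-12)
  expect_equal(build_unit_cost(cost_ingredients(other_consumables_cost = 100), fx),
               120 / fx, tolerance = 1e-12)
  # staff time and overhead carry no VAT
  expect_equal(build_unit_cost(cost_ingredients(staff_minutes = 30,
                                                salary_rate = 2,
                                                overhead = 40), fx),
               100 / fx, tolerance = 1e-12)
  expect_error(cost_ingredients(drug_cost = -1), "non-negative")
  expect_error(build_unit_cost(cost_ingredients(), fx_rate = 0), "fx_rate")
})

test_that("spend is unit cost times people, to the cent", {
  expect_equal(compute_spend(0.66, 0), 0)
  expect_equal(compute_spend(0.66, 41833), 27609.78)
  expect_equal(compute_spend(3.80, 3344), 12707.20)
})

test_that("treatment mix reproduces the published in-care accounting", {
  mix <- derive_treatment_mix(40000, 8600, 1 / 3, 0.08)
  expect_equal(mix$non_pharma, 3200)
  expect_equal(mix$oral_only, 28200)
  expect_equal(mix$insulin_plus_oral, 2867)
  expect_equal(mix$insulin_only, 5733)
  expect_equal(mix$oral_copay_eligible, 31067)

  all_insulin <- derive_treatment_mix(500, 500, 0, 0)
  expect_equal(all_insulin$oral_copay_eligible, 0)
  expect_equal(all_insulin$insulin_only, 500)

  small <- derive_treatment_mix(100, 30, 0.5, 0.10)
  expect_equal(small$non_pharma, 10)
  expect_equal(small$oral_only, 60)
  expect_equal(small$insulin_plus_oral, 15)
  expect_equal(small$oral_copay_eligible, 75)

  expect_error(derive_treatment_mix(100, 99, 0, 0.5), "inconsistent")
  expect_error(derive_treatment_mix(100, 150, 0, 0), "exceed")
})

test_that("treatment-mix invariants hold over random admissible inputs", {
  set.seed(7)
  for (i in 1:200) {
    total <- sample(1000:100000, 1)
    insulin <- sample(0:total, 1)
    f_io <- runif(1)
    f_np <- runif(1, 0, max(0, (total - insulin) / total))
    mix <- tryCatch(derive_treatment_mix(total, insulin, f_io, f_np),
                    error = function(e) NULL)
    if (is.null(mix)) next # rounding can push oral_only below 0 at the edge
    expect_equal(mix$insulin_only + mix$insulin_plus_oral,
                     mix$insulin_total)
    expect_equal(mix$non_pharma + mix$oral_only + mix$insulin_total,
                     mix$total_in_care)
    expect_equal(mix$oral_copay_eligible,
                     mix$oral_only + mix$insulin_plus_oral)
    expect_true(all(unlist(mix) >= 0))
  }
})

test_that("monitoring totals match the published table within display rounding", {
  tot <- monitoring_totals(poltava_monitoring_table())
  expect_equal(sum(tot$cells$people), 40000)
  # grand total equals the sum of its cells exactly, by construction
  expect_identical(tot$grand_total_usd, sum(tot$cells$total_usd))
  # printed grand total is 1,965,801 (from unrounded unit costs)
  expect_equal(tot$grand_total_usd, 1965801, tolerance = 0.001)
  # one cell from the displayed two-decimal unit cost
  oral_ctrl <- tot$cells$total_usd[tot$cells$group == "oral" &
                                     tot$cells$status == "controlled"]
  expect_equal(oral_ctrl, 216660.60)
  expect_equal(monitoring_totals(make_monitoring(rep(0, 6)))$grand_total_usd, 0)
})

test_that("monitoring-cost gaps match the published comparisons", {
  t <- poltava_monitoring_table()
  oral <- monitoring_cost_gap(t, "oral")
  expect_equal(oral$difference_usd, 27.24)
  expect_equal(oral$ratio, 52.85 / 25.61) # about twice as high
  insulin <- monitoring_cost_gap(t, "insulin")
  expect_equal(round(100 * (insulin$ratio - 1)), 61) # 61% higher
  np <- monitoring_cost_gap(t, "non_pharma")
  expect_equal(np$ratio, 28.28 / 24.48, tolerance = 1e-12) # 15.5% higher
  for (g in c("non_pharma", "oral", "insulin")) {
    expect_gt(monitoring_cost_gap(t, g)$ratio, 1)
  }
  zero <- make_monitoring(rep(1, 6))
  zero$unit_cost_usd[zero$group == "oral"] <- 0
  expect_error(monitoring_cost_gap(zero, "oral"), "undefined")
})

test_that("monitoring table validation enforces its six-cell structure", {
  t <- poltava_monitoring_table()
  expect_error(monitoring_table(t[-1, ]), "six")
  bad <- t
  bad$unit_cost_usd[bad$group == "oral" & bad$status == "controlled"] <- 99
  expect_error(monitoring_table(bad), "uncontrolled")
})

test_that("the published ledger is internally consistent within 1.5%", {
  audit <- recompute_ledger(poltava_cost_ledger())
  expect_true(all(audit$consistent))
  expect_true(all(audit$rel_diff < 0.015))
  # a corrupted line gets flagged
  bad <- poltava_cost_ledger()
  bad$spend_usd[1] <- bad$spend_usd[1] * 2
  expect_false(all(recompute_ledger(bad)$consistent))
})
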