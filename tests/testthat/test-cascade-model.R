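test_that("effective_rate scales proportionally with coverage and clips at 1", {
  expect_equal(effective_rate(0.2, 0.5, 0.5), 0.2) # baseline coverage
  expect_equal(effective_rate(0.2, 1.0, 0.5), 0.4)
  expect_equal(effective_rate(0.8, 1.0, 0.5), 1.0) # clipped
  expect_equal(effective_rate(0.3, 0, 0.5), 0)
  expect_error(effective_rate(0.2, 0.5, 0), "zero baseline")
})

test_that("a step with no flows, incidence or mortality leaves the state unchanged", {
  m <- toy_model(rab = 0, rbc = 0)
  s0 <- cascade_state(2016, c(A = 10, B = 5, C = 1, death = 0))
  s1 <- cascade_step(s0, m, dt = 0.25)
  expect_equal(s1$counts, s0$counts)
  expect_equal(s1$time, 2016.25)
})

test_that("people are conserved at every step, including deaths and incidence", {
  set.seed(41)
  for (rep in 1:20) {
    m <- toy_model(rab = runif(1, 0, 0.8), rbc = runif(1, 0, 0.8),
                   incidence = runif(1, 0, 500), mortality = runif(1, 0, 0.1))
    s <- cascade_state(0, c(A = runif(1, 0, 1e4), B = runif(1, 0, 1e4),
                            C = runif(1, 0, 1e4), death = 0))
    dt <- sample(c(0.05, 0.25, 0.5), 1)
    s1 <- cascade_step(s, m, dt)
    inc <- m$demography$annual_incident_cases * dt
    # deaths land in the sink, so the grand total only grows by incidence
    expect_equal(sum(s1$counts), sum(s$counts) + inc,
                 tolerance = 1e-9)
    # live-compartment balance: in + incidence - deaths = out
    deaths <- s1$counts[["death"]] - s$counts[["death"]]
    live0 <- sum(s$counts) - s$counts[["death"]]
    live1 <- sum(s1$counts) - s1$counts[["death"]]
    expect_equal(live1, live0 + inc - deaths, tolerance = 1e-9)
    expect_true(all(s1$counts >= 0))
  }
})

test_that("a single decaying compartment follows the discrete exponential", {
  r <- 0.3
  m <- toy_model(rab = r, rbc = 0)
  s <- cascade_state(0, c(A = 1000, B = 0, C = 0, death = 0))
  for (dt in c(0.1, 0.01)) {
    traj <- cascade_project(s, m, end_year = 1, dt = dt)
    expect_equal(traj$A[nrow(traj)], 1000 * (1 - r * dt)^(1 / dt),
                 tolerance = 1e-12)
  }
  # and approaches the continuous-time limit as dt -> 0
  fine <- cascade_project(s, m, end_year = 1, dt = 0.001)
  expect_equal(fine$A[nrow(fine)], 1000 * exp(-r), tolerance = 1e-3)
})

test_that("too-large time steps are rejected rather than producing negative flows", {
  m <- toy_model(rab = 0.9, rbc = 0, mortality = 0.2)
  s <- cascade_state(0, c(A = 100, B = 0, C = 0, death = 0))
  expect_error(cascade_step(s, m, dt = 1), "time step too large")
  expect_silent(cascade_step(s, m, dt = 0.5))
})

test_that("projection honours its length and first-element contracts", {
  m <- toy_model()
  s <- cascade_state(2016, c(A = 100, B = 0, C = 0, death = 0))
  one <- cascade_project(s, m, end_year = 2016)
  expect_equal(nrow(one), 1)
  expect_equal(unlist(one[1, -1]), s$counts)
  five <- cascade_project(s, m, end_year = 2020, dt = 1)
  expect_equal(nrow(five), 5)
  expect_equal(five$time, 2016:2020)
  expect_equal(unlist(five[1, -1]), s$counts)
})

test_that("downstream compartments of a pure chain are non-decreasing", {
  m <- toy_model(rab = 0.4, rbc = 0.3) # no incidence, no mortality
  s <- cascade_state(0, c(A = 1000, B = 0, C = 0, death = 0))
  traj <- cascade_project(s, m, end_year = 4, dt = 0.1)
  expect_true(all(diff(traj$C) >= -1e-12))
  expect_true(all(diff(traj$A) <= 1e-12))
})

test_that("projection matches an independent matrix-power oracle", {
  m <- toy_model(rab = 0.35, rbc = 0.15, incidence = 120, mortality = 0.02)
  counts <- c(A = 5000, B = 300, C = 40, death = 0)
  s <- cascade_state(0, counts)
  dt <- 0.25
  traj <- cascade_project(s, m, end_year = 3, dt = dt)
  mort <- c(A = 0.02, B = 0.02, C = 0.02, death = 0)
  expected <- oracle_project(counts, m$transitions, mort, 120,
                             "A", "death", dt, n_steps = 12)
  expect_equal(unlist(traj[nrow(traj), -1]), expected, tolerance = 1e-6)
})

test_that("coverage on a driven transition scales its flow", {
  m <- cascade_model(
    compartments = data.frame(id = c("u", "s", "death"),
                              terminal = c(FALSE, FALSE, TRUE)),
    transitions = data.frame(source = "u", target = "s", base_rate = 0.2,
                             driver = "screening"),
    demography = list(annual_incident_cases = 0, background_mortality = 0,
                      entry_compartment = "u", death_compartment = "death"))
  st <- cascade_state(0, c(u = 1000, s = 0, death = 0))
  base <- cascade_step(st, m, 0.25)
  doubled <- cascade_step(st, m, 0.25,
                          coverage = c(screening = 0.6),
                          reference_coverage = c(screening = 0.3))
  expect_equal(doubled$counts[["s"]], 2 * base$counts[["s"]])
  # missing reference coverage for a driven flow is an error
  expect_error(cascade_step(st, m, 0.25, coverage = c(screening = 0.6)),
               "reference_coverage")
})

test_that("model validation catches malformed definitions", {
  comp <- data.frame(id = c("a", "b", "death"),
                     terminal = c(FALSE, FALSE, TRUE))
  dem <- list(annual_incident_cases = 0, background_mortality = 0,
              entry_compartment = "a", death_compartment = "death")
  expect_error(cascade_model(comp,
                             data.frame(source = "a", target = "a",
                                        base_rate = 0.1), dem),
               "self-transitions")
  expect_error(cascade_model(comp,
                             data.frame(source = "a", target = "b",
                                        base_rate = 1.2), dem),
               "base_rate")
  expect_error(cascade_model(comp,
                             data.frame(source = c("a", "a"),
                                        target = c("b", "death"),
                                        base_rate = c(0.7, 0.6)), dem),
               "outflow")
  # state / model compartment mismatch
  m <- toy_model()
  expect_error(cascade_step(cascade_state(0, c(X = 1)), m, 0.1),
               "do not match")
})
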