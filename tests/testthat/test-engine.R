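# Transition structure and cohort trace.

test_that("the state space has 9 states closed under adding a disease", {
  ss <- state_space()
  expect_length(ss$states, 9)
  expect_length(ss$masks, 8)
  for (m in ss$masks)
    for (bit in c(1L, 2L, 4L))
      expect_true(bitwOr(m, bit) %in% ss$masks)  # lattice closure
})

test_that("transition rows are proper distributions with death handled first", {
  hz <- list(dementia = 0.02, mi = 0.01, stroke = 0.015,
             mortality = c(cvd = 0.01, other = 0.02))
  # death is absorbing
  dead <- transition_row("death", hz)
  expect_equal(dead$successors[["death"]], 1)
  expect_equal(sum(dead$events), 0)
  # zero hazards keep the cohort in place
  zero <- list(dementia = 0, mi = 0, stroke = 0,
               mortality = c(cvd = 0, other = 0))
  stay <- transition_row(c("mi"), zero)
  expect_equal(stay$successors[["mi"]], 1)
  # distributions sum to one from every alive state
  for (masks in list(character(0), "dementia", c("mi", "stroke"),
                     c("dementia", "mi", "stroke"))) {
    tr <- transition_row(masks, hz)
    expect_equal(sum(tr$successors), 1, tolerance = 1e-12)
    expect_equal(sum(tr$deaths), tr$successors[["death"]], tolerance = 1e-12)
  }
  # present diseases recur without changing state
  tr <- transition_row("mi", hz)
  expect_gt(tr$events[["mi"]], 0)
  expect_equal(tr$successors[["dem"]] + tr$successors[["str"]], 0)
})

test_that("transition row matches a seeded microsimulation within 3 SE", {
  hz <- list(dementia = 0.03, mi = 0.02, stroke = 0.04,
             mortality = c(cvd = 0.015, other = 0.025))
  tr <- transition_row(character(0), hz)
  n <- 2e5
  set.seed(4242)
  p_die <- 1 - exp(-sum(hz$mortality))
  died <- runif(n) < p_die
  surv_n <- sum(!died)
  on <- sapply(c("dementia", "mi", "stroke"), function(d)
    runif(surv_n) < 1 - exp(-hz[[d]]))
  mask <- on[, 1] * 1 + on[, 2] * 2 + on[, 3] * 4
  counts <- tabulate(mask + 1, nbins = 8) / n
  names9 <- c("atrisk", "dem", "mi", "dem_mi", "str", "dem_str", "mi_str",
              "dem_mi_str")
  for (k in 1:8) {
    p <- tr$successors[[names9[k]]]
    se <- sqrt(max(p * (1 - p), 1e-12) / n)
    expect_lt(abs(counts[k] - p), 3 * se + 1e-9)
  }
  se_d <- sqrt(p_die * (1 - p_die) / n)
  expect_lt(abs(mean(died) - tr$successors[["death"]]), 3 * se_d)
  # marginal event expectations
  for (j in 1:3) {
    d <- c("dementia", "mi", "stroke")[j]
    phat <- sum(on[, j]) / n
    se <- sqrt(tr$events[[d]] * (1 - tr$events[[d]]) / n)
    expect_lt(abs(phat - tr$events[[d]]), 3 * se)
  }
})

test_that("a null intervention reproduces standard of care exactly", {
  b <- random_mini_bundle(99)
  b$composite <- list(dementia = 1, cvd = c(male = 1, female = 1))
  soc <- run_cohort(b, "standard_of_care", horizon_age = 85)
  int <- run_cohort(b, "intervention", horizon_age = 85)
  expect_equal(trace_occupancy(int), trace_occupancy(soc), tolerance = 1e-14)
  expect_equal(trace_events(int), trace_events(soc), tolerance = 1e-14)
  expect_equal(unname(scale_events(soc) - scale_events(int)), rep(0, 3))
})

test_that("with zero mortality the dementia trace follows the geometric
           closed form", {
  b <- random_mini_bundle(7)
  b$life_table$rate <- 0
  r <- 0.05
  b$incidence$dementia <- list(intercept = log(r), b_age = 0, b_sex = 0,
                               history_rr = numeric(0))
  b$incidence$mi$intercept <- -50
  b$incidence$stroke$intercept <- -50
  b$cohort$cells <- data.frame(age_low = 60, age_high = 60, sex = "female",
                               mi_history = FALSE, stroke_history = FALSE,
                               proportion = 1)
  tr <- run_cohort(b, "standard_of_care", horizon_age = 80)
  p <- 1 - exp(-r)
  occ <- trace_occupancy(tr)
  for (t in c(1, 5, 10, 20)) {
    in_dem <- sum(occ[t + 1, c("dem", "dem_mi", "dem_str", "dem_mi_str")])
    expect_equal(in_dem, 1 - (1 - p)^t, tolerance = 1e-10)
  }
  expect_equal(sum(trace_deaths(tr)), 0)
})

test_that("with MI and stroke switched off the 9-state model equals a 3-state
           reference", {
  b <- random_mini_bundle(21)
  b$incidence$mi$intercept <- -100
  b$incidence$stroke$intercept <- -100
  b$cohort$cells <- data.frame(age_low = 62, age_high = 62, sex = "male",
                               mi_history = FALSE, stroke_history = FALSE,
                               proportion = 1)
  tr <- run_cohort(b, "standard_of_care", horizon_age = 90)
  # independent 3-state loop: at-risk / dementia / dead
  atr <- 1; dem <- 0; dead <- 0
  occ <- trace_occupancy(tr)
  for (t in 0:(90 - 62 - 1)) {
    a <- 62 + t
    base <- calibrate_baseline_mortality(b$life_table, b$prevalence,
                                         b$mortality_rr, a, "male")
    m0 <- sum(base)
    m1 <- sum(state_mortality(base, "dementia", b$mortality_rr))
    p0 <- 1 - exp(-m0); p1 <- 1 - exp(-m1)
    pon <- 1 - exp(-incidence_rate(b$incidence$dementia, a, "male"))
    dead <- dead + atr * p0 + dem * p1
    newdem <- atr * (1 - p0) * pon
    atr <- atr * (1 - p0) * (1 - pon)
    dem <- dem * (1 - p1) + newdem
    expect_equal(unname(occ[t + 2, "atrisk"]), atr, tolerance = 1e-12)
    expect_equal(unname(occ[t + 2, "dem"]), dem, tolerance = 1e-12)
    expect_equal(unname(occ[t + 2, "death"]), dead, tolerance = 1e-12)
  }
})

test_that("base-case traces conserve probability with monotone death", {
  for (b in list(uk_bundle(), china_bundle())) {
    for (strat in c("standard_of_care", "intervention")) {
      tr <- run_cohort(b, strat)
      expect_trace_valid(tr)
      agg <- trace_occupancy(tr)
      expect_equal(unname(rowSums(agg)), rep(1, nrow(agg)), tolerance = 1e-10)
      expect_true(all(diff(agg[, "death"]) >= -1e-12))
    }
  }
})

test_that("event scaling is linear and prevented events are the difference", {
  b <- uk_bundle()
  soc <- run_cohort(b, "standard_of_care")
  int <- run_cohort(b, "intervention")
  ev1 <- scale_events(soc, 1)
  expect_equal(scale_events(soc, 1e5), ev1 * 1e5)
  s <- economic_summary(b, soc, int)
  expect_equal(s$prevented_events, scale_events(soc) - scale_events(int))
  expect_true(all(s$prevented_events > 0))  # protective effect prevents events
  expect_error(scale_events(soc, -1), "cohort_size")
})

test_that("tidy trace export matches the aggregates", {
  b <- random_mini_bundle(3, n_strata = 1)
  tr <- run_cohort(b, "standard_of_care", horizon_age = 75)
  td <- trace_tidy(tr)
  occ <- trace_occupancy(tr)
  expect_equal(td$occupancy$proportion[td$occupancy$state == "death"],
               unname(occ[, "death"]))
  ev <- trace_events(tr)
  expect_equal(td$events$expected_count[td$events$event_type == "mi"],
               unname(ev[, "mi"]))
})
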