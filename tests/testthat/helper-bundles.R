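# Test helpers: small randomised bundles and a cached default bundle.

# default bundles are deterministic; build once per test run
uk_bundle <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- default_bundle("uk")
    b
  }
})

china_bundle <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- default_bundle("china")
    b
  }
})

random_prevalence <- function(ages, pmax = 0.3) {
  grid <- expand.grid(age = ages, sex = c("male", "female"),
                      disease = c("dementia", "mi", "stroke"),
                      stringsAsFactors = FALSE)
  grid$prevalence <- runif(nrow(grid), 0, pmax)
  grid
}

# a compact random bundle: 1-3 single-age strata, random epidemiology,
# random economics; intended for fast property sweeps
random_mini_bundle <- function(seed, n_strata = 2) {
  set.seed(seed)
  rglm <- function() list(intercept = runif(1, -13, -6.5),
                          b_age = runif(1, 0, 0.12),
                          b_sex = runif(1, -0.4, 0.4),
                          history_rr = setNames(runif(3, 1, 6),
                                                c("dementia", "mi", "stroke")))
  inc <- list(dementia = rglm(), mi = rglm(), stroke = rglm())
  inc$dementia$history_rr <- inc$dementia$history_rr[c("mi", "stroke")]
  lt <- make_life_table(alpha = 10^runif(1, -6, -5),
                        beta = runif(1, 0.08, 0.13),
                        sex_ratio = runif(1, 1.2, 1.8), ages = 55:100)
  ages <- sort(sample(58:72, n_strata))
  cells <- data.frame(
    age_low = ages, age_high = ages,
    sex = sample(c("male", "female"), n_strata, replace = TRUE),
    mi_history = sample(c(TRUE, FALSE), n_strata, replace = TRUE),
    stroke_history = sample(c(TRUE, FALSE), n_strata, replace = TRUE),
    proportion = NA_real_
  )
  w <- runif(n_strata); cells$proportion <- w / sum(w)
  mk_rr <- function() setNames(runif(3, 1, 6), c("dementia", "mi", "stroke"))
  b <- list(
    country = "synthetic",
    incidence = inc,
    incidence_multiplier = 1,
    life_table = lt,
    prevalence = random_prevalence(55:100),
    mortality_rr = list(cvd = mk_rr(), other = mk_rr()),
    cohort = list(cells = cells, cohort_size = 1e5),
    utility = list(genpop = c(0.95, 0.02, 2.6e-4, -3.3e-5),
                   ratio = c(dementia = runif(1, 0.6, 1),
                             mi = runif(1, 0.6, 1),
                             stroke = runif(1, 0.6, 1)),
                   event_disutility = c(mi = -runif(1, 0, 0.05),
                                        stroke = -runif(1, 0, 0.05))),
    costs = list(
      disease = data.frame(
        disease = rep(c("dementia", "mi", "stroke"), each = 2),
        payer = rep(c("health_sector", "informal"), 3),
        post_year1 = runif(6, 0, 10000),
        year1_additional = runif(6, 0, 10000)),
      intervention = list(platform_per_user_year = runif(1, 0, 50),
                          coaching_per_user_year = runif(1, 0, 1000),
                          duration_years = 10)),
    waning = waning_policy(10, 0.10, "none"),
    composite = list(dementia = runif(1, 0.8, 1.05),
                     cvd = c(male = runif(1, 0.9, 1.05),
                             female = runif(1, 0.9, 1.05))),
    settings = list(discount_rate_costs = 0.035, discount_rate_effects = 0.035,
                    wtp = 20000, max_age = 100L, currency = "GBP"),
    provenance = c(all = "synthetic")
  )
  validate_bundle(b)
}

# trace-level structural checks shared by several tests
expect_trace_valid <- function(trace, tol = 1e-10) {
  for (s in trace$strata) {
    sums <- rowSums(s$occ)
    expect_true(all(abs(sums - 1) < tol))
    expect_true(all(diff(s$occ[, "death"]) >= -tol))
    expect_true(all(s$occ >= -tol & s$occ <= 1 + tol))
  }
}
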