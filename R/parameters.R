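# Parameter bundle: domain types, validation, file I/O and bundled defaults.

DISEASES <- c("dementia", "mi", "stroke")
SEXES <- c("male", "female")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Numeric indicator for sex (male = 1, female = 0)
#'
#' Every regression in the package codes sex with this convention.
#'
#' @param sex `"male"` or `"female"` (vectorised).
#' @return Integer vector of 0/1.
#' @export
sex_indicator <- function(sex) {
  sex <- match.arg(sex, SEXES, several.ok = TRUE)
  as.integer(sex == "male")
}

#' Construct a risk-factor effect
#'
#' One modifiable risk factor: its per-unit relative risk in a risk score
#' (optionally sex-specific), the trial mean change in the factor and the
#' standard error of that change.  Binary factors express `delta` as a change
#' in prevalence proportion; continuous factors use natural units.
#'
#' @param name Factor label.
#' @param rr_per_unit Relative risk per unit of the factor; either a single
#'   number or a named vector `c(male = , female = )`.
#' @param delta Trial mean change in factor units (negative = reduction).
#' @param se_delta Standard error of `delta` (same units), `>= 0`.
#' @param unit Unit label, e.g. `"mmHg"`, `"proportion"`.
#' @return An object of class `risk_factor`.
#' @export
risk_factor <- function(name, rr_per_unit, delta, se_delta = 0, unit = "") {
  if (any(rr_per_unit <= 0)) stopf("risk_factor '%s': rr_per_unit must be > 0", name)
  if (se_delta < 0) stopf("risk_factor '%s': se_delta must be >= 0", name)
  if (length(rr_per_unit) > 1 && !all(SEXES %in% names(rr_per_unit)))
    stopf("risk_factor '%s': sex-specific rr_per_unit needs names 'male' and 'female'", name)
  structure(
    list(name = name, rr_per_unit = rr_per_unit, delta = delta,
         se_delta = se_delta, unit = unit),
    class = "risk_factor"
  )
}

#' Construct a per-disease risk-model specification
#'
#' @param disease `"dementia"`, `"mi"` or `"stroke"` (or `"cvd"` for a model
#'   shared by MI and stroke).
#' @param factors List of [risk_factor()] objects with unique names.
#' @param label Provenance tag, e.g. `"CAIDE"`, `"QRISK1"`, `"user-override"`.
#' @return An object of class `risk_model`.
#' @export
risk_model <- function(disease, factors, label = "user") {
  nm <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(nm)) stopf("risk_model '%s': duplicate factor names", disease)
  structure(list(disease = disease, factors = factors, label = label),
            class = "risk_model")
}

#' Construct a waning policy
#'
#' Intervention effect and costs decay through annual non-adherence and stop
#' after `duration_years`.
#'
#' @param duration_years Maximum intervention duration in years (>= 0; may be
#'   `Inf` for lifetime provision).
#' @param annual_nonadherence Proportion quitting per year, in \[0, 1\].
#' @param post_duration_effect `"none"` (effect vanishes after the duration) or
#'   `"frozen"` (held at its last within-duration value).
#' @return An object of class `waning_policy`.
#' @export
waning_policy <- function(duration_years = 10, annual_nonadherence = 0.10,
                          post_duration_effect = c("none", "frozen")) {
  post_duration_effect <- match.arg(post_duration_effect)
  if (duration_years < 0) stopf("waning_policy: duration_years must be >= 0")
  if (annual_nonadherence < 0 || annual_nonadherence > 1)
    stopf("waning_policy: annual_nonadherence must be in [0, 1]")
  structure(list(duration_years = duration_years,
                 annual_nonadherence = annual_nonadherence,
                 post_duration_effect = post_duration_effect),
            class = "waning_policy")
}

# ---- validation ------------------------------------------------------------

check_glm <- function(g, disease) {
  need <- c("intercept", "b_age", "b_sex")
  for (f in need)
    if (!is.numeric(g[[f]])) stopf("incidence$%s$%s: missing or non-numeric", disease, f)
  if (is.null(g$b_age_sex)) g$b_age_sex <- 0
  if (is.null(g$history_rr)) g$history_rr <- numeric(0)
  if (any(g$history_rr <= 0))
    stopf("incidence$%s$history_rr: values must be > 0", disease)
  g$disease <- disease
  g
}

check_life_table <- function(lt) {
  need <- c("age", "sex", "rate", "cvd_fraction")
  if (!all(need %in% names(lt))) stopf("life_table: needs columns %s", paste(need, collapse = ", "))
  if (any(lt$rate < 0)) stopf("life_table$rate: negative mortality rate")
  if (any(lt$cvd_fraction < 0 | lt$cvd_fraction > 1))
    stopf("life_table$cvd_fraction: must be in [0, 1]")
  lt
}

check_prevalence <- function(pr) {
  need <- c("age", "sex", "disease", "prevalence")
  if (!all(need %in% names(pr))) stopf("prevalence: needs columns %s", paste(need, collapse = ", "))
  if (any(pr$prevalence < 0 | pr$prevalence > 1))
    stopf("prevalence$prevalence: must be in [0, 1]")
  pr
}

check_cohort <- function(co) {
  cells <- co$cells
  need <- c("age_low", "age_high", "sex", "mi_history", "stroke_history", "proportion")
  if (!all(need %in% names(cells)))
    stopf("cohort$cells: needs columns %s", paste(need, collapse = ", "))
  if (any(cells$proportion < 0)) stopf("cohort$cells$proportion: negative proportion")
  if (abs(sum(cells$proportion) - 1) > 1e-9)
    stopf("cohort$cells$proportion: must sum to 1 (got %.12f)", sum(cells$proportion))
  if (is.null(co$cohort_size) || co$cohort_size <= 0)
    stopf("cohort$cohort_size: must be > 0")
  co
}

check_mortality_rr <- function(mr) {
  for (cause in c("cvd", "other")) {
    v <- mr[[cause]]
    if (!all(DISEASES %in% names(v)))
      stopf("mortality_rr$%s: needs named values for dementia, mi, stroke", cause)
    if (any(v <= 0)) stopf("mortality_rr$%s: values must be > 0", cause)
  }
  mr
}

check_utility <- function(ut) {
  if (length(ut$genpop) != 4)
    stopf("utility$genpop: needs 4 coefficients (constant, male, age, age^2)")
  if (any(ut$ratio <= 0 | ut$ratio > 1))
    stopf("utility$ratio: ratios must be in (0, 1]")
  if (any(ut$event_disutility > 0))
    stopf("utility$event_disutility: must be <= 0")
  ut
}

check_costs <- function(cp) {
  tab <- cp$disease
  need <- c("disease", "payer", "post_year1", "year1_additional")
  if (!all(need %in% names(tab)))
    stopf("costs$disease: needs columns %s", paste(need, collapse = ", "))
  if (any(tab$post_year1 < 0)) stopf("costs$disease$post_year1: negative cost")
  if (any(tab$year1_additional < 0)) stopf("costs$disease$year1_additional: negative cost")
  iv <- cp$intervention
  if (any(unlist(iv[c("platform_per_user_year", "coaching_per_user_year")]) < 0))
    stopf("costs$intervention: negative cost")
  cp
}

check_settings <- function(st) {
  if (st$discount_rate_costs < 0 || st$discount_rate_effects < 0)
    stopf("settings: discount rates must be >= 0")
  if (st$wtp <= 0) stopf("settings$wtp: must be > 0")
  st
}

#' Validate a parameter bundle
#'
#' Runs every type invariant; errors name the offending field.  Missing
#' optional history relative risks default to 1 at use time.
#'
#' @param bundle A parameter bundle (list of class `cua_bundle`).
#' @return The validated bundle (invisibly the same object).
#' @export
validate_bundle <- function(bundle) {
  for (d in DISEASES) bundle$incidence[[d]] <- check_glm(bundle$incidence[[d]], d)
  bundle$life_table <- check_life_table(bundle$life_table)
  bundle$prevalence <- check_prevalence(bundle$prevalence)
  bundle$cohort <- check_cohort(bundle$cohort)
  bundle$mortality_rr <- check_mortality_rr(bundle$mortality_rr)
  bundle$utility <- check_utility(bundle$utility)
  bundle$costs <- check_costs(bundle$costs)
  bundle$settings <- check_settings(bundle$settings)
  if (!inherits(bundle$waning, "waning_policy"))
    bundle$waning <- do.call(waning_policy, bundle$waning)
  comp <- bundle$composite
  if (any(unlist(comp) <= 0)) stopf("composite: relative risks must be > 0")
  # mortality rates must exist for every cohort start age through max_age
  ages <- seq(min(bundle$cohort$cells$age_low), bundle$settings$max_age - 1L)
  have <- sort(unique(bundle$life_table$age))
  if (!all(ages %in% have))
    stopf("life_table: ages must cover %d through %d", min(ages), max(ages))
  class(bundle) <- "cua_bundle"
  bundle
}

# ---- bundled defaults ------------------------------------------------------

#' Default parameter bundle for a country setting
#'
#' Returns the full model input set for the UK or China.  Published scalar
#' inputs (incidence regression coefficients, history and mortality relative
#' risks, utility regressions and ratios, annual and event costs, intervention
#' prices, discount rates, willingness to pay) are transcribed constants.
#' Tables that are not published — the life table, the prevalence table used
#' for mortality calibration, the starting-cohort distribution and the
#' per-factor trial-effect table — are synthetic stand-ins generated by the
#' `make_*` fixture functions and flagged as such in `$provenance`.
#'
#' @param country `"uk"` or `"china"` (case-insensitive).
#' @return A validated bundle of class `cua_bundle`.
#' @examples
#' b <- default_bundle("uk")
#' b$incidence$dementia$intercept   # -12.40
#' b$costs$intervention$coaching_per_user_year
#' @export
default_bundle <- function(country = c("uk", "china")) {
  country <- match.arg(tolower(country), c("uk", "china"))
  if (country == "uk") {
    incidence <- list(
      dementia = list(intercept = -12.40, b_age = 0.11, b_sex = 0.16,
                      history_rr = c(stroke = 1.71)),
      mi = list(intercept = -7.50, b_age = 0.03, b_sex = 0.39,
                history_rr = c(mi = 7.59)),
      stroke = list(intercept = -6.84, b_age = 0.02, b_sex = 0.20,
                    history_rr = c(mi = 2.11, stroke = 4.51))
    )
    mortality_rr <- list(
      cvd   = c(dementia = 5.82, mi = 1.43, stroke = 1.27),
      other = c(dementia = 5.82, mi = 1.43, stroke = 1.27)
    )
    utility <- list(
      genpop = c(constant = 0.9508566, male = 0.0212126,
                 age = 0.0002587, age2 = -0.0000332),
      ratio = c(dementia = 0.876, mi = 0.923, stroke = 0.839),
      event_disutility = c(mi = -0.025, stroke = -0.048)
    )
    cost_tab <- data.frame(
      disease = rep(DISEASES, each = 2),
      payer = rep(c("health_sector", "informal"), 3),
      post_year1 = c(7973, 10028, 276, 0, 4116, 6953),
      year1_additional = c(0, 0, 6554, 0, 10714, 0)
    )
    intervention <- list(platform_per_user_year = 5,
                         coaching_per_user_year = 800,
                         duration_years = 10)
    settings <- list(discount_rate_costs = 0.035, discount_rate_effects = 0.035,
                     wtp = 20000, max_age = 100L, currency = "GBP")
    life_table <- make_life_table(alpha = 5.5e-6, beta = 0.114, sex_ratio = 1.6,
                                  ages = 40:100)
  } else {
    incidence <- list(
      dementia = list(intercept = -13.91, b_age = 0.13, b_sex = 0.34,
                      history_rr = numeric(0)),
      mi = list(intercept = -9.62, b_age = 0.06, b_sex = -0.34,
                history_rr = numeric(0)),
      stroke = list(intercept = -9.82, b_age = 0.08, b_sex = -0.26,
                    history_rr = numeric(0))
    )
    mortality_rr <- list(
      cvd   = c(dementia = 3.02, mi = 4.3, stroke = 4.3),
      other = c(dementia = 3.02, mi = 4.3, stroke = 4.3)
    )
    utility <- list(
      genpop = c(constant = 0.9091741, male = 0.0050488,
                 age = 0.0023842, age2 = -0.0000319),
      ratio = c(dementia = 0.764, mi = 0.939, stroke = 0.774),
      event_disutility = c(mi = -0.025, stroke = -0.048)
    )
    cost_tab <- data.frame(
      disease = rep(DISEASES, each = 2),
      payer = rep(c("health_sector", "informal"), 3),
      post_year1 = c(20973, 65826, 2920, 0, 10401, 17570),
      year1_additional = c(0, 0, 29196, 0, 11752, 0)
    )
    intervention <- list(platform_per_user_year = 38,
                         coaching_per_user_year = 510,
                         duration_years = 10)
    settings <- list(discount_rate_costs = 0.05, discount_rate_effects = 0.05,
                     wtp = 81419, max_age = 100L, currency = "CNY")
    life_table <- make_life_table(alpha = 7.0e-6, beta = 0.113, sex_ratio = 1.5,
                                  ages = 40:100)
  }
  effects <- make_trial_effect_table()
  prevalence <- make_prevalence_table(incidence, life_table, mortality_rr)
  cohort <- make_starting_cohort()
  bundle <- list(
    country = country,
    incidence = incidence,
    incidence_multiplier = 1,
    life_table = life_table,
    prevalence = prevalence,
    mortality_rr = mortality_rr,
    cohort = cohort,
    utility = utility,
    costs = list(disease = cost_tab, intervention = intervention),
    waning = waning_policy(duration_years = 10, annual_nonadherence = 0.10,
                           post_duration_effect = "none"),
    effects = effects,
    composite = list(
      dementia = composite_relative_risk(effects$dementia),
      cvd = c(male = composite_relative_risk(effects$cvd, "male"),
              female = composite_relative_risk(effects$cvd, "female"))
    ),
    settings = settings,
    provenance = c(incidence = "published", mortality_rr = "published",
                   utility = "published", costs = "published",
                   settings = "published", waning = "published",
                   life_table = "fixture", prevalence = "fixture",
                   cohort = "fixture", effects = "fixture")
  )
  validate_bundle(bundle)
}

# ---- file I/O --------------------------------------------------------------

df_to_list <- function(df) lapply(as.list(df), function(x) unname(x))

# yaml drops names on atomic vectors; store them as maps instead
listify_named <- function(x) {
  if (is.atomic(x) && !is.null(names(x))) as.list(x)
  else if (is.list(x)) lapply(x, listify_named)
  else x
}

list_to_df <- function(lst) as.data.frame(lapply(lst, unlist),
                                          stringsAsFactors = FALSE)

#' Write a parameter bundle to a YAML file
#'
#' @param bundle A validated bundle.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  doc <- unclass(bundle)
  doc$life_table <- df_to_list(doc$life_table)
  doc$prevalence <- df_to_list(doc$prevalence)
  doc$cohort$cells <- df_to_list(doc$cohort$cells)
  doc$costs$disease <- df_to_list(doc$costs$disease)
  doc$waning <- unclass(doc$waning)
  doc$effects <- lapply(doc$effects, function(spec) {
    list(disease = spec$disease, label = spec$label,
         factors = lapply(spec$factors, function(f) unclass(f)))
  })
  doc <- listify_named(doc)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Load a parameter bundle from a YAML file
#'
#' Reads a document written by [write_bundle()] (or hand-authored to the same
#' schema), reconstructs all domain types and validates every invariant.
#'
#' @param path YAML file.
#' @return A validated bundle of class `cua_bundle`.
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stopf("load_bundle: file '%s' not found", path)
  doc <- yaml::read_yaml(path)
  for (sec in c("incidence", "life_table", "prevalence", "cohort",
                "mortality_rr", "utility", "costs", "settings", "waning"))
    if (is.null(doc[[sec]])) stopf("load_bundle: mandatory section '%s' missing", sec)
  doc$life_table <- list_to_df(doc$life_table)
  doc$prevalence <- list_to_df(doc$prevalence)
  doc$cohort$cells <- list_to_df(doc$cohort$cells)
  doc$costs$disease <- list_to_df(doc$costs$disease)
  for (d in DISEASES) {
    hr <- doc$incidence[[d]]$history_rr
    doc$incidence[[d]]$history_rr <- if (length(hr)) unlist(hr) else numeric(0)
  }
  doc$mortality_rr <- lapply(doc$mortality_rr, unlist)
  doc$utility$genpop <- unlist(doc$utility$genpop)
  doc$utility$ratio <- unlist(doc$utility$ratio)
  doc$utility$event_disutility <- unlist(doc$utility$event_disutility)
  doc$waning <- do.call(waning_policy, doc$waning)
  if (!is.null(doc$effects))
    doc$effects <- lapply(doc$effects, function(spec) {
      risk_model(spec$disease,
                 lapply(spec$factors, function(f) {
                   rr <- unlist(f$rr_per_unit)
                   risk_factor(f$name, rr, f$delta, f$se_delta, f$unit)
                 }),
                 spec$label)
    })
  doc$composite <- lapply(doc$composite, unlist)
  doc$provenance <- unlist(doc$provenance)
  validate_bundle(doc)
}

#' Read a life table from CSV
#'
#' Expected columns: `age`, `sex`, `rate`, `cvd_fraction`.
#' @param path CSV file.
#' @return A validated life-table data frame.
#' @export
read_life_table <- function(path)
  check_life_table(utils::read.csv(path, stringsAsFactors = FALSE))

#' Read a prevalence table from CSV
#'
#' Expected columns: `age`, `sex`, `disease`, `prevalence`.
#' @param path CSV file.
#' @return A validated prevalence data frame.
#' @export
read_prevalence_table <- function(path)
  check_prevalence(utils::read.csv(path, stringsAsFactors = FALSE))

#' Read a starting cohort from CSV
#'
#' Expected columns: `age_low`, `age_high`, `sex`, `mi_history`,
#' `stroke_history`, `proportion`.  The cohort size defaults to 100,000.
#' @param path CSV file.
#' @param cohort_size Scaling count for event reporting.
#' @return A validated starting-cohort list.
#' @export
read_starting_cohort <- function(path, cohort_size = 1e5) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  cells$mi_history <- as.logical(cells$mi_history)
  cells$stroke_history <- as.logical(cells$stroke_history)
  check_cohort(list(cells = cells, cohort_size = cohort_size))
}

#' Read a risk-model specification from CSV
#'
#' Expected columns: `factor`, `rr_per_unit_male`, `rr_per_unit_female`,
#' `delta`, `se_delta`, `unit`.  Equal male/female columns collapse to a
#' sex-invariant relative risk.
#' @param path CSV file.
#' @param disease Disease label for the model.
#' @param label Provenance tag.
#' @return A `risk_model` object.
#' @export
read_risk_model <- function(path, disease, label = basename(path)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  factors <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    rr <- if (isTRUE(all.equal(r$rr_per_unit_male, r$rr_per_unit_female)))
      r$rr_per_unit_male
    else c(male = r$rr_per_unit_male, female = r$rr_per_unit_female)
    risk_factor(r$factor, rr, r$delta, r$se_delta, r$unit)
  })
  risk_model(disease, factors, label)
}
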