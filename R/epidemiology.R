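# State- and age-specific disease incidence and cause-specific mortality,
# with calibration of disease-free mortality from general-population life
# tables.

lt_lookup <- function(life_table, age, sex) {
  i <- which(life_table$age == age & life_table$sex == sex)
  if (!length(i)) stopf("life_table: no row for age %s, sex %s", age, sex)
  life_table[i[1], ]
}

prev_lookup <- function(prevalence, age, sex) {
  out <- c(dementia = 0, mi = 0, stroke = 0)
  sel <- prevalence$age == age & prevalence$sex == sex
  if (any(sel)) {
    sub <- prevalence[sel, ]
    out[sub$disease] <- sub$prevalence
  }
  out
}

#' Disease incidence rate for a state
#'
#' Log-linear incidence: `exp(intercept + b_age * age + b_sex * male)` times
#' the product of history relative risks for the diseases already present in
#' the state, times the intervention relative risk.  Dementia onset is 0 in
#' any state that already includes dementia (the history is absorbing); MI and
#' stroke recur through their own history relative risks.
#'
#' @param glm Incidence model: list with `intercept`, `b_age`, `b_sex`,
#'   optional `b_age_sex` (default 0) and a named `history_rr` vector (absent
#'   diseases default to relative risk 1).
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param state Character vector of diseases present, subset of
#'   `c("dementia", "mi", "stroke")`; `character(0)` for the at-risk state.
#' @param intervention_rr Multiplicative intervention relative risk.
#' @return Rate per person-year.
#' @examples
#' glm <- list(intercept = -12.40, b_age = 0.11, b_sex = 0.16,
#'             history_rr = c(stroke = 1.71), disease = "dementia")
#' incidence_rate(glm, 70, "male", character(0))
#' @export
incidence_rate <- function(glm, age, sex, state = character(0),
                           intervention_rr = 1) {
  if (identical(glm$disease, "dementia") && "dementia" %in% state) return(0)
  male <- sex_indicator(sex)
  bas <- if (is.null(glm$b_age_sex)) 0 else glm$b_age_sex
  rate <- exp(glm$intercept + glm$b_age * age + glm$b_sex * male +
                bas * age * male)
  hr <- glm$history_rr
  for (d in state) if (d %in% names(hr)) rate <- rate * hr[[d]]
  rate * intervention_rr
}

#' Convert a rate to a per-cycle probability
#'
#' Constant-hazard conversion `1 - exp(-rate * cycle_length)`.
#'
#' @param rate Rate per person-year, `>= 0`; vectorised.
#' @param cycle_length Cycle length in years.
#' @return Probability in \[0, 1).
#' @export
rate_to_probability <- function(rate, cycle_length = 1) {
  if (any(rate < 0)) stopf("rate_to_probability: negative rate")
  1 - exp(-rate * cycle_length)
}

state_prev_weights <- function(pv) {
  # joint prevalence of the 8 disease-history combinations assuming
  # independence of the three marginal prevalences
  w <- numeric(8)
  for (m in 0:7) {
    p <- 1
    p <- p * if (bitwAnd(m, 1L) > 0) pv[["dementia"]] else 1 - pv[["dementia"]]
    p <- p * if (bitwAnd(m, 2L) > 0) pv[["mi"]] else 1 - pv[["mi"]]
    p <- p * if (bitwAnd(m, 4L) > 0) pv[["stroke"]] else 1 - pv[["stroke"]]
    w[m + 1] <- p
  }
  w
}

state_mort_rr <- function(rrs, cause) {
  # per-state product of the cause's history relative risks, states as
  # bitmasks 0..7 (1 = dementia, 2 = mi, 4 = stroke)
  v <- rrs[[cause]]
  out <- numeric(8)
  for (m in 0:7) {
    r <- 1
    if (bitwAnd(m, 1L) > 0) r <- r * v[["dementia"]]
    if (bitwAnd(m, 2L) > 0) r <- r * v[["mi"]]
    if (bitwAnd(m, 4L) > 0) r <- r * v[["stroke"]]
    out[m + 1] <- r
  }
  out
}

#' Calibrate disease-free mortality from a general-population life table
#'
#' Splits the all-cause life-table rate at `(age, sex)` into CVD and other
#' cause rates via the table's CVD death fraction, then divides each cause
#' rate by the prevalence-weighted mean mortality relative risk over the 8
#' disease-history states (joint prevalence from independence of the three
#' marginal prevalences; relative risk of a combination state is the product
#' of its single-disease relative risks).  By construction, recombining the
#' calibrated state-specific rates with the same weights reproduces the
#' life-table cause rate exactly.
#'
#' @param life_table Life-table data frame (`age`, `sex`, `rate`,
#'   `cvd_fraction`).
#' @param prevalence Prevalence data frame (`age`, `sex`, `disease`,
#'   `prevalence`).
#' @param rrs Mortality relative risks: list with named vectors `cvd` and
#'   `other` over the three diseases.
#' @param age,sex Stratum.
#' @return Named vector `c(cvd = , other = )` of disease-free mortality rates.
#' @export
calibrate_baseline_mortality <- function(life_table, prevalence, rrs, age, sex) {
  row <- lt_lookup(life_table, age, sex)
  cause_rates <- c(cvd = row$rate * row$cvd_fraction,
                   other = row$rate * (1 - row$cvd_fraction))
  pv <- prev_lookup(prevalence, age, sex)
  w <- state_prev_weights(pv)
  out <- vapply(c("cvd", "other"), function(cause) {
    mean_rr <- sum(w * state_mort_rr(rrs, cause))
    cause_rates[[cause]] / mean_rr
  }, 0)
  names(out) <- c("cvd", "other")
  out
}

#' State-specific cause mortality rates
#'
#' Multiplies each disease-free cause rate by the product of that cause's
#' mortality relative risks for every disease present in the state.
#'
#' @param baseline Named vector `c(cvd = , other = )` of disease-free rates.
#' @param state Character vector of diseases present.
#' @param rrs Mortality relative risks (as in
#'   [calibrate_baseline_mortality()]).
#' @return Named vector `c(cvd = , other = )`.
#' @export
state_mortality <- function(baseline, state, rrs) {
  out <- baseline
  for (cause in c("cvd", "other"))
    for (d in state) out[[cause]] <- out[[cause]] * rrs[[cause]][[d]]
  out
}
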