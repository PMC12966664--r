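# Economic outcomes: person-years, utilities, discounted QALYs and costs,
# ICER, incremental net health benefit and headroom pricing.
#
# Accounting conventions (see the methods vignette): state membership is
# counted at end-of-cycle occupancy, events accrue within the cycle they
# occur, there is no half-cycle correction, and discounting uses
# (1 + r)^-t with t = 0 for the first cycle.

#' Person-years lived with and without each disease
#'
#' Sums end-of-cycle occupancy over all cycles, per starting person.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @return List with `alive` (total person-years) and named vectors `with`
#'   and `without` per disease; `with + without = alive` for every disease.
#' @export
person_years <- function(trace) {
  has <- sapply(DISEASES, function(d) vapply(STATE_MASKS, mask_has, TRUE, d))
  alive <- 0
  with_d <- stats::setNames(numeric(3), DISEASES)
  for (s in trace$strata) {
    occ <- s$occ[-1, 1:8, drop = FALSE]   # end-of-cycle rows
    alive <- alive + s$weight * sum(occ)
    for (d in DISEASES)
      with_d[d] <- with_d[d] + s$weight * sum(occ[, has[, d], drop = FALSE])
  }
  list(alive = alive, with = with_d, without = alive - with_d)
}

#' Utility of a health state
#'
#' General-population utility from a quadratic age regression
#' (`constant + male + age + age^2` coefficients, male = 1), multiplied by
#' the utility ratio of every disease present in the state (multiplicative
#' multimorbidity combination; an additive-decrement combination is available
#' via `combine`).  Death has utility 0; results are clamped to \[0, 1\].
#'
#' @param params Utility parameters (`genpop`, `ratio`, `event_disutility`).
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param state Character vector of diseases present, or `"death"`.
#' @param combine `"multiplicative"` (default) or `"additive"`.
#' @return Utility in \[0, 1\].
#' @export
state_utility <- function(params, age, sex, state = character(0),
                          combine = c("multiplicative", "additive")) {
  combine <- match.arg(combine)
  if (identical(state, "death") || "death" %in% state) return(0)
  g <- params$genpop
  u <- g[[1]] + g[[2]] * sex_indicator(sex) + g[[3]] * age + g[[4]] * age^2
  mult <- if (combine == "multiplicative") prod(params$ratio[state])
  else max(0, 1 - sum(1 - params$ratio[state]))
  min(1, max(0, u * mult))
}

# utility of the 8 alive states at one (age, sex)
state_utility_vec <- function(params, age, sex, combine = "multiplicative") {
  vapply(STATE_MASKS, function(m)
    state_utility(params, age, sex, mask_to_state(m), combine), 0)
}

#' Discounted quality-adjusted life years of a trace
#'
#' Per cycle, end-of-cycle occupancy times state utility, plus expected MI
#' and stroke events times their event-year disutility, discounted at the
#' effects rate.
#'
#' @param trace A `cohort_trace`.
#' @param params Utility parameters.
#' @param settings Economic settings (uses `discount_rate_effects`).
#' @param combine Multimorbidity combination rule, see [state_utility()].
#' @return Discounted QALYs per starting person.
#' @export
qalys <- function(trace, params, settings, combine = "multiplicative") {
  r <- settings$discount_rate_effects
  total <- 0
  for (s in trace$strata) {
    n <- nrow(s$events)
    if (!n) next
    disc <- (1 + r)^(-(seq_len(n) - 1))
    uy <- vapply(seq_len(n), function(t1) {
      u <- state_utility_vec(params, s$start_age + t1, s$sex, combine)
      sum(s$occ[t1 + 1, 1:8] * u)
    }, 0)
    ev <- s$events[, "mi"] * params$event_disutility[["mi"]] +
      s$events[, "stroke"] * params$event_disutility[["stroke"]]
    total <- total + s$weight * sum((uy + ev) * disc)
  }
  total
}

cost_lookup <- function(tab, disease, payer, column) {
  i <- which(tab$disease == disease & tab$payer == payer)
  if (!length(i)) 0 else tab[[column]][i[1]]
}

#' Discounted costs of a trace by category
#'
#' Disease history person-time accrues the annual post-year-1 cost per payer;
#' each expected event (onset or recurrence) adds the one-off year-1
#' additional cost on top.  Under the intervention strategy, platform and
#' coaching per-user-year prices accrue for cycles `t < duration_years`,
#' scaled by the adherent fraction and the start-of-cycle surviving
#' proportion.  All amounts are discounted at the cost rate.
#'
#' @param trace A `cohort_trace`.
#' @param cost_params Cost parameters (`disease` table and `intervention`
#'   prices).
#' @param policy A [waning_policy()] (drives the adherence weighting).
#' @param settings Economic settings (uses `discount_rate_costs`).
#' @param strategy Strategy the costs are accrued for; defaults to the
#'   trace's own strategy.
#' @return Named vector: `health_care`, `informal_care`, `platform`,
#'   `coaching`, `total` (per starting person).
#' @export
discounted_costs <- function(trace, cost_params, policy, settings,
                             strategy = trace$strategy) {
  r <- settings$discount_rate_costs
  tab <- cost_params$disease
  has <- sapply(DISEASES, function(d) vapply(STATE_MASKS, mask_has, TRUE, d))
  annual <- sapply(c("health_sector", "informal"), function(p)
    vapply(STATE_MASKS, function(m)
      sum(vapply(mask_to_state(m), cost_lookup, 0, tab = tab, payer = p,
                 column = "post_year1"), 0), 0))     # 8 x 2
  event_cost <- sapply(c("health_sector", "informal"), function(p)
    vapply(DISEASES, cost_lookup, 0, tab = tab, payer = p,
           column = "year1_additional"))             # 3 x 2
  iv <- cost_params$intervention
  dur <- min(iv$duration_years %||% policy$duration_years,
             policy$duration_years)
  coaching_years <- iv$coaching_years %||% dur
  out <- c(health_care = 0, informal_care = 0, platform = 0, coaching = 0)
  for (s in trace$strata) {
    n <- nrow(s$events)
    if (!n) next
    disc <- (1 + r)^(-(seq_len(n) - 1))
    occ_end <- s$occ[-1, 1:8, drop = FALSE]
    hc <- occ_end %*% annual[, "health_sector"] + s$events %*% event_cost[, "health_sector"]
    ic <- occ_end %*% annual[, "informal"] + s$events %*% event_cost[, "informal"]
    out["health_care"] <- out["health_care"] + s$weight * sum(hc * disc)
    out["informal_care"] <- out["informal_care"] + s$weight * sum(ic * disc)
    if (identical(strategy, "intervention")) {
      tt <- seq_len(n) - 1
      alive_start <- rowSums(s$occ[seq_len(n), 1:8, drop = FALSE])
      adh <- adherent_fraction(tt, policy)
      expo <- adh * alive_start * disc
      out["platform"] <- out["platform"] +
        s$weight * iv$platform_per_user_year * sum(expo[tt < dur])
      out["coaching"] <- out["coaching"] +
        s$weight * iv$coaching_per_user_year * sum(expo[tt < coaching_years])
    }
  }
  c(out, total = sum(out))
}

# discounted adherence-weighted survivor exposure (per person), the annuity
# multiplying any per-user-year intervention price
intervention_exposure <- function(trace, policy, settings) {
  r <- settings$discount_rate_costs
  total <- 0
  for (s in trace$strata) {
    n <- nrow(s$events)
    if (!n) next
    tt <- seq_len(n) - 1
    alive_start <- rowSums(s$occ[seq_len(n), 1:8, drop = FALSE])
    expo <- adherent_fraction(tt, policy) * alive_start * (1 + r)^(-tt)
    total <- total + s$weight * sum(expo[tt < policy$duration_years])
  }
  total
}

#' Incremental cost-effectiveness ratio and net health benefit
#'
#' `ICER = dC / dE` (NA when `dE = 0`) and `iNHB = dE - dC / wtp`.
#'
#' @param delta_qalys Incremental discounted QALYs per person (Ei - Ec).
#' @param delta_costs Incremental discounted costs per person (Ci - Cc).
#' @param wtp Willingness to pay per QALY (lambda).
#' @return A single number.
#' @export
incremental_net_health_benefit <- function(delta_qalys, delta_costs, wtp) {
  if (wtp <= 0) stopf("incremental_net_health_benefit: wtp must be > 0")
  delta_qalys - delta_costs / wtp
}

#' @rdname incremental_net_health_benefit
#' @export
incremental_cer <- function(delta_qalys, delta_costs) {
  if (delta_qalys == 0) return(NA_real_)
  delta_costs / delta_qalys
}

#' Economic summary of two strategies
#'
#' Computes cumulative events, person-years, discounted QALYs and costs for
#' the standard-of-care and intervention traces, and the incremental
#' cost-effectiveness ratio `ICER = (Ci - Cc) / (Ei - Ec)` and incremental
#' net health benefit `iNHB = (Ei - Ec) - (Ci - Cc) / lambda`.  The ICER is
#' reported as `NA` (flagged, not an error) when the QALY difference is zero.
#'
#' @param bundle The parameter bundle both traces were run from.
#' @param trace_soc,trace_int Traces for standard of care and intervention.
#' @return Object of class `econ_summary`.
#' @export
economic_summary <- function(bundle, trace_soc, trace_int) {
  stopifnot(trace_soc$horizon_age == trace_int$horizon_age)
  per_strategy <- function(trace) {
    list(
      events = scale_events(trace),
      person_years = person_years(trace),
      qalys = qalys(trace, bundle$utility, bundle$settings),
      costs = discounted_costs(trace, bundle$costs, bundle$waning,
                               bundle$settings)
    )
  }
  soc <- per_strategy(trace_soc)
  int <- per_strategy(trace_int)
  dE <- int$qalys - soc$qalys
  dC <- int$costs[["total"]] - soc$costs[["total"]]
  lambda <- bundle$settings$wtp
  icer <- incremental_cer(dE, dC)
  structure(list(
    country = bundle$country,
    soc = soc, intervention = int,
    prevented_events = soc$events - int$events,
    delta_qalys = dE, delta_costs = dC,
    icer = icer, icer_defined = dE != 0,
    inhb = incremental_net_health_benefit(dE, dC, lambda),
    wtp = lambda,
    cohort_size = bundle$cohort$cohort_size
  ), class = "econ_summary")
}

#' @export
print.econ_summary <- function(x, ...) {
  cat(sprintf("Economic summary (%s, cohort %s)\n", x$country,
              format(x$cohort_size, big.mark = ",")))
  ev <- rbind(`standard of care` = x$soc$events,
              intervention = x$intervention$events,
              prevented = x$prevented_events)
  print(round(ev, 0))
  cat(sprintf("QALYs/person: %.4f vs %.4f (delta %+.5f)\n",
              x$soc$qalys, x$intervention$qalys, x$delta_qalys))
  cat(sprintf("Costs/person: %.0f vs %.0f (delta %+.0f)\n",
              x$soc$costs[["total"]], x$intervention$costs[["total"]],
              x$delta_costs))
  cat(sprintf("ICER: %s   iNHB: %.4f (wtp %.0f)\n",
              if (x$icer_defined) sprintf("%.0f", x$icer) else "undefined",
              x$inhb, x$wtp))
  invisible(x)
}

#' Headroom intervention price
#'
#' The maximum per-user-year intervention price (replacing both platform and
#' coaching) at which the incremental net health benefit is exactly zero.
#' Solved by bisection to a relative tolerance, and cross-checkable against
#' the closed form `(lambda * dE - dC_disease) / exposure` (iNHB is linear in
#' the price), where the exposure is the discounted adherence-weighted
#' survivor annuity.
#'
#' @param bundle A parameter bundle.
#' @param effect_scope `"dementia_only"` (CVD effect removed, as in a
#'   dementia-focused pricing exercise) or `"all"`.
#' @param horizon_age Optional horizon override.
#' @param tol Relative bisection tolerance.
#' @return List with `cost` (bisection), `closed_form`, `delta_qalys`,
#'   `delta_disease_costs` and `exposure`.
#' @export
headroom_cost <- function(bundle, effect_scope = c("dementia_only", "all"),
                          horizon_age = NULL, tol = 1e-6) {
  effect_scope <- match.arg(effect_scope)
  b <- bundle
  if (effect_scope == "dementia_only")
    b$composite$cvd <- c(male = 1, female = 1)
  soc <- run_cohort(b, "standard_of_care", horizon_age)
  int <- run_cohort(b, "intervention", horizon_age)
  dE <- qalys(int, b$utility, b$settings) - qalys(soc, b$utility, b$settings)
  if (dE <= 0) stopf("headroom_cost: non-positive QALY gain (%.3g)", dE)
  dis <- function(trace) {
    cc <- discounted_costs(trace, b$costs, b$waning, b$settings,
                           strategy = "standard_of_care")  # disease costs only
    cc[["health_care"]] + cc[["informal_care"]]
  }
  dC_dis <- dis(int) - dis(soc)
  A <- intervention_exposure(int, b$waning, b$settings)
  lambda <- b$settings$wtp
  closed <- (lambda * dE - dC_dis) / A
  f <- function(price) dE - (dC_dis + price * A) / lambda
  lo <- 0; hi <- max(1, 2 * abs(closed))
  while (f(hi) > 0) hi <- hi * 2
  if (f(lo) < 0) stopf("headroom_cost: iNHB negative even at zero price")
  while ((hi - lo) > tol * max(1, abs(hi))) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) lo <- mid else hi <- mid
  }
  list(cost = (lo + hi) / 2, closed_form = closed, delta_qalys = dE,
       delta_disease_costs = dC_dis, exposure = A)
}
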