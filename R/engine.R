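# Nine-state transition structure and the yearly cohort trace.
#
# Alive states are the 8 subsets of {dementia, mi, stroke}, encoded as
# bitmasks 0..7 (1 = dementia, 2 = mi, 4 = stroke) at indices 1..8; index 9
# is the absorbing death state.  Transitions to death are handled first;
# conditional on survival each absent disease onsets independently, so
# simultaneous multi-disease onset within a cycle is permitted.

STATE_MASKS <- 0:7
STATE_NAMES <- c("atrisk", "dem", "mi", "dem_mi", "str", "dem_str",
                 "mi_str", "dem_mi_str", "death")

mask_has <- function(mask, disease) {
  bit <- c(dementia = 1L, mi = 2L, stroke = 4L)[[disease]]
  bitwAnd(mask, bit) > 0
}

mask_to_state <- function(mask)
  DISEASES[c(mask_has(mask, "dementia"), mask_has(mask, "mi"),
             mask_has(mask, "stroke"))]

state_to_mask <- function(state) {
  m <- 0L
  if ("dementia" %in% state) m <- m + 1L
  if ("mi" %in% state) m <- m + 2L
  if ("stroke" %in% state) m <- m + 4L
  m
}

#' The model state space
#'
#' @return List with the 9 state names, the alive-state bitmasks and the
#'   disease membership of each alive state.
#' @export
state_space <- function() {
  list(states = STATE_NAMES,
       masks = STATE_MASKS,
       membership = lapply(STATE_MASKS, mask_to_state))
}

# ---- single-state transition ----------------------------------------------

#' One-cycle transition distribution for a single state
#'
#' Death is resolved first from the summed cause rates; conditional on
#' survival, each absent disease onsets independently with its converted
#' probability and diseases already present produce expected recurrent events
#' (`rate * cycle_length * survivor mass`) without changing state.
#'
#' @param state Character vector of diseases present (alive state) or
#'   `"death"`.
#' @param hazards List with per-person-year rates: `dementia`, `mi`, `stroke`
#'   (onset rates for absent diseases, recurrence rates for present MI or
#'   stroke) and `mortality = c(cvd = , other = )`.
#' @param cycle_length Cycle length in years.
#' @return List with `successors` (named probability vector over the 9
#'   states), `events` (expected `dementia`/`mi`/`stroke` events per unit of
#'   starting occupancy) and `deaths` (`c(cvd = , other = )`).
#' @export
transition_row <- function(state, hazards, cycle_length = 1) {
  succ <- stats::setNames(numeric(9), STATE_NAMES)
  events <- c(dementia = 0, mi = 0, stroke = 0)
  deaths <- c(cvd = 0, other = 0)
  if (identical(state, "death") || "death" %in% state) {
    succ["death"] <- 1
    return(list(successors = succ, events = events, deaths = deaths))
  }
  m_total <- sum(hazards$mortality)
  p_die <- rate_to_probability(m_total, cycle_length)
  if (m_total > 0) deaths <- p_die * hazards$mortality / m_total
  surv <- 1 - p_die
  absent <- setdiff(DISEASES, state)
  if ("dementia" %in% state) absent <- setdiff(absent, "dementia")
  p_on <- stats::setNames(rep(0, 3), DISEASES)
  if (length(absent))
    p_on[absent] <- rate_to_probability(unlist(hazards[absent]), cycle_length)
  # successor mass: product over absent diseases of onset / no-onset
  n <- length(absent)
  combos <- if (n) expand.grid(rep(list(c(FALSE, TRUE)), n)) else
    data.frame(row.names = 1)
  for (i in seq_len(max(1L, nrow(combos)))) {
    on <- if (n) absent[unlist(combos[i, ])] else character(0)
    p <- prod(p_on[on], 1 - p_on[setdiff(absent, on)])
    target <- STATE_NAMES[state_to_mask(c(state, on)) + 1]
    succ[target] <- succ[target] + surv * p
  }
  succ["death"] <- p_die
  # events: marginal onset expectations plus recurrences among survivors
  events["dementia"] <- surv * p_on[["dementia"]]
  for (d in c("mi", "stroke")) {
    events[d] <- surv * p_on[[d]]
    if (d %in% state) events[d] <- events[d] + surv * hazards[[d]] * cycle_length
  }
  list(successors = succ, events = events, deaths = deaths)
}

# ---- precomputation --------------------------------------------------------

# per-sex grids used by the cycle loop: onset base rates, history
# multipliers, calibrated baseline mortality and state mortality multipliers
precompute_hazards <- function(incidence, life_table, prevalence,
                               mortality_rr, sex, ages,
                               incidence_multiplier = 1) {
  male <- sex_indicator(sex)
  r0 <- sapply(DISEASES, function(d) {
    g <- incidence[[d]]
    bas <- if (is.null(g$b_age_sex)) 0 else g$b_age_sex
    exp(g$intercept + g$b_age * ages + g$b_sex * male + bas * ages * male) *
      incidence_multiplier
  })                                              # |ages| x 3
  histmult <- sapply(DISEASES, function(d) {
    hr <- incidence[[d]]$history_rr
    vapply(STATE_MASKS, function(m) {
      r <- 1
      for (h in DISEASES)
        if (mask_has(m, h) && h %in% names(hr)) r <- r * hr[[h]]
      r
    }, 0)
  })                                              # 8 x 3
  dem_allowed <- vapply(STATE_MASKS, function(m) !mask_has(m, "dementia"), TRUE)
  baseline <- t(vapply(ages, function(a)
    calibrate_baseline_mortality(life_table, prevalence, mortality_rr, a, sex),
    c(cvd = 0, other = 0)))                       # |ages| x 2
  mortmult <- cbind(cvd = state_mort_rr(mortality_rr, "cvd"),
                    other = state_mort_rr(mortality_rr, "other"))
  has <- sapply(DISEASES, function(d) vapply(STATE_MASKS, mask_has, TRUE, d))
  list(ages = ages, r0 = r0, histmult = histmult, dem_allowed = dem_allowed,
       baseline = baseline, mortmult = mortmult, has = has)
}

# ---- stratum simulation ----------------------------------------------------

# Deterministic trace of one (start age, sex, start state) stratum.
# rr_fun(t) returns c(dementia, mi, stroke) intervention relative risks for
# cycle t (0-indexed).  Returns end-of-cycle occupancy (rows 0..T over 9
# states), per-cycle events (T x 3) and deaths by cause (T x 2).
simulate_stratum <- function(haz, start_age, start_mask, n_cycles, rr_fun,
                             cycle_length = 1) {
  occ <- matrix(0, n_cycles + 1, 9,
                dimnames = list(NULL, STATE_NAMES))
  occ[1, start_mask + 1] <- 1
  events <- matrix(0, n_cycles, 3, dimnames = list(NULL, DISEASES))
  deaths <- matrix(0, n_cycles, 2, dimnames = list(NULL, c("cvd", "other")))
  has <- haz$has
  for (t in seq_len(n_cycles) - 1L) {
    a_idx <- match(start_age + t, haz$ages)
    cur <- occ[t + 1, ]
    alive <- cur[1:8]
    rr_int <- rr_fun(t)
    # death first
    m_cvd <- haz$baseline[a_idx, 1] * haz$mortmult[, 1]
    m_oth <- haz$baseline[a_idx, 2] * haz$mortmult[, 2]
    m_tot <- m_cvd + m_oth
    p_die <- 1 - exp(-m_tot * cycle_length)
    dead_mass <- alive * p_die
    frac_cvd <- ifelse(m_tot > 0, m_cvd / m_tot, 0)
    deaths[t + 1, ] <- c(sum(dead_mass * frac_cvd),
                         sum(dead_mass * (1 - frac_cvd)))
    surv <- alive - dead_mass
    # per-state onset/recurrence rates
    r <- sweep(haz$histmult, 2, haz$r0[a_idx, ] * rr_int, `*`)  # 8 x 3
    p_dem <- ifelse(haz$dem_allowed, 1 - exp(-r[, 1] * cycle_length), 0)
    p_mi_on <- ifelse(has[, "mi"], 0, 1 - exp(-r[, 2] * cycle_length))
    p_str_on <- ifelse(has[, "stroke"], 0, 1 - exp(-r[, 3] * cycle_length))
    events[t + 1, 1] <- sum(surv * p_dem)
    events[t + 1, 2] <- sum(surv * p_mi_on) +
      sum(surv[has[, "mi"]] * r[has[, "mi"], 2] * cycle_length)
    events[t + 1, 3] <- sum(surv * p_str_on) +
      sum(surv[has[, "stroke"]] * r[has[, "stroke"], 3] * cycle_length)
    # distribute survivors over onset combinations (independent onsets)
    nxt <- numeric(9)
    for (s in 1:8) {
      if (surv[s] == 0) next
      pd <- p_dem[s]; pm <- p_mi_on[s]; ps <- p_str_on[s]
      base <- STATE_MASKS[s]
      for (od in 0:1) for (om in 0:1) for (os in 0:1) {
        p <- (if (od) pd else 1 - pd) * (if (om) pm else 1 - pm) *
          (if (os) ps else 1 - ps)
        if (p == 0) next
        tgt <- bitwOr(base, od * 1L + om * 2L + os * 4L) + 1L
        nxt[tgt] <- nxt[tgt] + surv[s] * p
      }
    }
    nxt[9] <- cur[9] + sum(dead_mass)
    occ[t + 2, ] <- nxt
  }
  list(occ = occ, events = events, deaths = deaths)
}

# ---- cohort run ------------------------------------------------------------

expand_cohort <- function(cohort) {
  cells <- cohort$cells
  out <- list()
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, ]
    ages <- seq(r$age_low, r$age_high)
    mask <- state_to_mask(c(if (isTRUE(as.logical(r$mi_history))) "mi",
                            if (isTRUE(as.logical(r$stroke_history))) "stroke"))
    for (a in ages)
      out[[length(out) + 1]] <- list(start_age = a, sex = r$sex,
                                     start_mask = mask,
                                     weight = r$proportion / length(ages))
  }
  out
}

#' Run the cohort model for one strategy
#'
#' Expands the starting cohort into (integer age, sex, disease-history)
#' strata (uniform within age bands), simulates each stratum with yearly
#' cycles up to the horizon age, and collects the per-stratum traces with
#' their starting weights.  Under the intervention strategy the composite
#' relative risks wane per [effective_rr()]; under standard of care all
#' intervention relative risks are 1.  Fully deterministic.
#'
#' @param bundle A validated parameter bundle (see [default_bundle()]).
#' @param strategy `"standard_of_care"` or `"intervention"`.
#' @param horizon_age Stop age; defaults to `bundle$settings$max_age`.
#' @return An object of class `cohort_trace`: list of per-stratum traces plus
#'   weights, strategy and horizon.
#' @export
run_cohort <- function(bundle, strategy = c("standard_of_care", "intervention"),
                       horizon_age = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(horizon_age)) horizon_age <- bundle$settings$max_age
  if (horizon_age - 1 > max(bundle$life_table$age))
    stopf("run_cohort: life table does not cover horizon age %d", horizon_age)
  strata <- expand_cohort(bundle$cohort)
  haz_by_sex <- list()
  ages <- seq(min(vapply(strata, `[[`, 0, "start_age")), horizon_age - 1L)
  out <- vector("list", length(strata))
  for (i in seq_along(strata)) {
    st <- strata[[i]]
    if (is.null(haz_by_sex[[st$sex]]))
      haz_by_sex[[st$sex]] <- precompute_hazards(
        bundle$incidence, bundle$life_table, bundle$prevalence,
        bundle$mortality_rr, st$sex, ages,
        incidence_multiplier = bundle$incidence_multiplier %||% 1)
    rr_fun <- if (strategy == "intervention") {
      comp_dem <- bundle$composite$dementia
      comp_cvd <- bundle$composite$cvd[[st$sex]]
      pol <- bundle$waning
      function(t) c(effective_rr(comp_dem, t, pol),
                    rep(effective_rr(comp_cvd, t, pol), 2))
    } else function(t) c(1, 1, 1)
    n_cycles <- horizon_age - st$start_age
    sim <- simulate_stratum(haz_by_sex[[st$sex]], st$start_age, st$start_mask,
                            n_cycles, rr_fun)
    out[[i]] <- c(st, sim)
  }
  structure(list(strata = out, strategy = strategy, horizon_age = horizon_age,
                 cohort_size = bundle$cohort$cohort_size),
            class = "cohort_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate state occupancy of a trace
#'
#' Weighted occupancy by cycle over the 9 states.  Strata whose horizon is
#' shorter than the longest stratum are carried forward at their final
#' occupancy, so every row sums to 1.
#'
#' @param trace A `cohort_trace`.
#' @return Matrix (cycles + 1) x 9; row `t + 1` is the end of cycle `t`.
#' @export
trace_occupancy <- function(trace) {
  max_t <- max(vapply(trace$strata, function(s) nrow(s$occ), 0L))
  agg <- matrix(0, max_t, 9, dimnames = list(NULL, STATE_NAMES))
  for (s in trace$strata) {
    occ <- s$occ
    if (nrow(occ) < max_t)
      occ <- rbind(occ, matrix(occ[nrow(occ), ], max_t - nrow(occ), 9,
                               byrow = TRUE))
    agg <- agg + s$weight * occ
  }
  agg
}

#' Aggregate expected events per cycle
#'
#' @param trace A `cohort_trace`.
#' @return Matrix cycles x 3 (`dementia`, `mi`, `stroke`) of expected events
#'   per starting person.
#' @export
trace_events <- function(trace) {
  max_t <- max(vapply(trace$strata, function(s) nrow(s$events), 0L))
  agg <- matrix(0, max_t, 3, dimnames = list(NULL, DISEASES))
  for (s in trace$strata) {
    ev <- s$events
    if (nrow(ev) < max_t) ev <- rbind(ev, matrix(0, max_t - nrow(ev), 3))
    agg <- agg + s$weight * ev
  }
  agg
}

#' Aggregate deaths per cycle by cause
#'
#' @param trace A `cohort_trace`.
#' @return Matrix cycles x 2 (`cvd`, `other`).
#' @export
trace_deaths <- function(trace) {
  max_t <- max(vapply(trace$strata, function(s) nrow(s$deaths), 0L))
  agg <- matrix(0, max_t, 2, dimnames = list(NULL, c("cvd", "other")))
  for (s in trace$strata) {
    d <- s$deaths
    if (nrow(d) < max_t) d <- rbind(d, matrix(0, max_t - nrow(d), 2))
    agg <- agg + s$weight * d
  }
  agg
}

#' Scale expected event proportions to a cohort
#'
#' @param trace A `cohort_trace`.
#' @param cohort_size Cohort scaling count; defaults to the bundle's.
#' @return Named vector of cumulative dementia onset, MI and stroke events
#'   (including recurrences) per `cohort_size` persons.
#' @export
scale_events <- function(trace, cohort_size = NULL) {
  cohort_size <- cohort_size %||% trace$cohort_size
  if (cohort_size <= 0) stopf("scale_events: cohort_size must be > 0")
  colSums(trace_events(trace)) * cohort_size
}

#' Export a trace as tidy data frames
#'
#' @param trace A `cohort_trace`.
#' @return List of two data frames: `occupancy` (cycle, state, proportion)
#'   and `events` (cycle, event_type, expected_count per person).
#' @export
trace_tidy <- function(trace) {
  occ <- trace_occupancy(trace)
  ev <- trace_events(trace)
  list(
    occupancy = data.frame(
      cycle = rep(seq_len(nrow(occ)) - 1L, times = 9),
      state = rep(STATE_NAMES, each = nrow(occ)),
      proportion = as.vector(occ)),
    events = data.frame(
      cycle = rep(seq_len(nrow(ev)) - 1L, times = 3),
      event_type = rep(DISEASES, each = nrow(ev)),
      expected_count = as.vector(ev))
  )
}
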