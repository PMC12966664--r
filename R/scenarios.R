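# Scenario grid, external-validity classification and tabular reports.

SCENARIO_KNOBS <- c("start_age", "sex", "horizon_age", "discount_rate",
                    "wtp", "cost_multiplier", "lifetime_full_adherence",
                    "without_coaching", "dementia_only", "no_cvd_history",
                    "rr_overrides", "incidence_uplift")

apply_scenario <- function(bundle, overrides) {
  unknown <- setdiff(names(overrides), SCENARIO_KNOBS)
  if (length(unknown))
    stopf("run_scenario: unknown knob(s): %s", paste(unknown, collapse = ", "))
  b <- bundle
  ov <- overrides
  if (!is.null(ov$sex) && is.null(ov$start_age))
    stopf("run_scenario: 'sex' requires 'start_age' (heterogeneity stratum)")
  if (!is.null(ov$start_age)) {
    sexes <- if (is.null(ov$sex)) SEXES else match.arg(ov$sex, SEXES)
    cells <- expand.grid(sex = sexes, stringsAsFactors = FALSE)
    cells <- data.frame(age_low = ov$start_age, age_high = ov$start_age,
                        sex = cells$sex, mi_history = FALSE,
                        stroke_history = FALSE,
                        proportion = 1 / length(sexes))
    b$cohort$cells <- cells
  }
  if (!is.null(ov$no_cvd_history) && isTRUE(ov$no_cvd_history)) {
    cells <- b$cohort$cells
    agg <- stats::aggregate(proportion ~ age_low + age_high + sex, cells, sum)
    agg$mi_history <- FALSE
    agg$stroke_history <- FALSE
    b$cohort$cells <- agg[, c("age_low", "age_high", "sex", "mi_history",
                              "stroke_history", "proportion")]
  }
  if (!is.null(ov$discount_rate)) {
    b$settings$discount_rate_costs <- ov$discount_rate
    b$settings$discount_rate_effects <- ov$discount_rate
  }
  if (!is.null(ov$wtp)) b$settings$wtp <- ov$wtp
  if (!is.null(ov$cost_multiplier)) {
    iv <- b$costs$intervention
    iv$platform_per_user_year <- iv$platform_per_user_year * ov$cost_multiplier
    iv$coaching_per_user_year <- iv$coaching_per_user_year * ov$cost_multiplier
    b$costs$intervention <- iv
  }
  if (isTRUE(ov$lifetime_full_adherence)) {
    b$waning <- waning_policy(duration_years = Inf, annual_nonadherence = 0,
                              post_duration_effect = b$waning$post_duration_effect)
    b$costs$intervention$duration_years <- Inf
  }
  if (isTRUE(ov$without_coaching))
    b$costs$intervention$coaching_years <- 1
  if (isTRUE(ov$dementia_only)) {
    # dementia-only model: MI and stroke are removed entirely (no incidence,
    # no effect), not merely stripped of the intervention effect
    b$composite$cvd <- c(male = 1, female = 1)
    b$incidence$mi$intercept <- -Inf
    b$incidence$stroke$intercept <- -Inf
  }
  if (!is.null(ov$rr_overrides)) {
    rro <- ov$rr_overrides
    if (!is.null(rro$dementia)) b$composite$dementia <- rro$dementia
    if (!is.null(rro$cvd)) {
      v <- rro$cvd
      b$composite$cvd <- if (length(v) == 1) c(male = v, female = v)
      else c(male = v[["male"]], female = v[["female"]])
    }
  }
  if (!is.null(ov$incidence_uplift))
    b$incidence_multiplier <- (b$incidence_multiplier %||% 1) * ov$incidence_uplift
  validate_bundle(b)
}

#' Run a scenario
#'
#' Applies a named set of overrides to a copy of the bundle (the base bundle
#' is never mutated), reruns both strategies and returns the economic
#' summary.  Supported knobs: `start_age` (+ optional `sex`), `horizon_age`,
#' `discount_rate`, `wtp`, `cost_multiplier`, `lifetime_full_adherence`,
#' `without_coaching`, `dementia_only`, `no_cvd_history`, `rr_overrides`
#' (list with `dementia` and/or `cvd`), `incidence_uplift`.  Unknown knobs
#' are rejected.
#'
#' @param bundle Base parameter bundle.
#' @param overrides Named list of scenario knobs (empty = base case).
#' @return An `econ_summary`, with the scenario recorded in
#'   `attr(, "scenario")`.
#' @export
run_scenario <- function(bundle, overrides = list()) {
  b <- apply_scenario(bundle, overrides)
  horizon <- overrides$horizon_age %||% b$settings$max_age
  soc <- run_cohort(b, "standard_of_care", horizon)
  int <- run_cohort(b, "intervention", horizon)
  out <- economic_summary(b, soc, int)
  attr(out, "scenario") <- overrides
  out
}

#' Classify simulated prevalence against observed confidence intervals
#'
#' A cell is `good` when the simulated value lies inside the observed
#' interval (bounds inclusive), `moderate` when it is outside but by no more
#' than one interval half-width beyond the violated bound (i.e. not more
#' than two times beyond the interval), and `poor` otherwise.
#'
#' @param simulated Data frame with key columns and a `prevalence` column.
#' @param observed Data frame with the same key columns plus `lo` and `hi`.
#' @return The merged data frame with a `validity` factor column.
#' @export
validate_prevalence <- function(simulated, observed) {
  keys <- setdiff(intersect(names(simulated), names(observed)),
                  c("prevalence", "lo", "hi"))
  if (!length(keys)) stopf("validate_prevalence: no shared key columns")
  m <- merge(simulated, observed, by = keys)
  if (nrow(m) < nrow(observed))
    stopf("validate_prevalence: %d observed cell(s) missing from simulation",
          nrow(observed) - nrow(m))
  hw <- (m$hi - m$lo) / 2
  v <- ifelse(m$prevalence >= m$lo & m$prevalence <= m$hi, "good",
              ifelse(m$prevalence >= m$lo - hw & m$prevalence <= m$hi + hw,
                     "moderate", "poor"))
  m$validity <- factor(v, levels = c("good", "moderate", "poor"))
  m
}

summary_rows <- function(s) {
  py_s <- s$soc$person_years; py_i <- s$intervention$person_years
  nhb <- function(side) side$qalys - side$costs[["total"]] / s$wtp
  rows <- rbind(
    data.frame(item = paste0(DISEASES, "_events_per_cohort"),
               soc = unname(s$soc$events),
               intervention = unname(s$intervention$events)),
    data.frame(item = paste0("person_years_with_", DISEASES),
               soc = unname(py_s$with), intervention = unname(py_i$with)),
    data.frame(item = paste0("person_years_without_", DISEASES),
               soc = unname(py_s$without), intervention = unname(py_i$without)),
    data.frame(item = "person_years_alive",
               soc = py_s$alive, intervention = py_i$alive),
    data.frame(item = "qalys", soc = s$soc$qalys,
               intervention = s$intervention$qalys),
    data.frame(item = paste0("cost_", names(s$soc$costs)),
               soc = unname(s$soc$costs),
               intervention = unname(s$intervention$costs)),
    data.frame(item = "net_health_benefit", soc = nhb(s$soc),
               intervention = nhb(s$intervention))
  )
  rows$difference <- rows$intervention - rows$soc
  rows$pct_difference <- ifelse(rows$soc != 0,
                                100 * rows$difference / rows$soc, NA)
  rows
}

config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(raw[-seq_len(14)], f)   # drop the serialization header
  unname(tools::md5sum(f))
}

#' Write tabular reports for one or more economic summaries
#'
#' Writes, per summary, a two-strategy outcome table with difference and
#' percent-difference columns; a combined scenario table of incremental
#' outcomes; and a JSON run manifest carrying the seed, a configuration hash
#' and any provenance flags.  Deterministic given identical inputs.
#'
#' @param summaries Named list of `econ_summary` objects (at least one).
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"json"` for the outcome tables.
#' @param seed Seed to record in the manifest.
#' @param provenance Optional named provenance flags (e.g.
#'   `bundle$provenance`) recorded in the manifest.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(summaries, dir, format = c("csv", "json"),
                         seed = NULL, provenance = NULL) {
  format <- match.arg(format)
  if (!length(summaries)) stopf("write_report: need at least one summary")
  if (is.null(names(summaries)))
    names(summaries) <- paste0("summary", seq_along(summaries))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(summaries)) {
    rows <- summary_rows(summaries[[nm]])
    f <- file.path(dir, paste0(nm, ".", format))
    if (format == "csv") utils::write.csv(rows, f, row.names = FALSE)
    else jsonlite::write_json(rows, f, digits = NA, dataframe = "rows")
    files <- c(files, f)
  }
  inc <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(scenario = nm,
               prevented_dementia = s$prevented_events[["dementia"]],
               prevented_mi = s$prevented_events[["mi"]],
               prevented_stroke = s$prevented_events[["stroke"]],
               delta_qalys = s$delta_qalys, delta_costs = s$delta_costs,
               icer = s$icer, inhb = s$inhb)
  }))
  f <- file.path(dir, paste0("scenarios.", format))
  if (format == "csv") utils::write.csv(inc, f, row.names = FALSE)
  else jsonlite::write_json(inc, f, digits = NA, dataframe = "rows")
  files <- c(files, f)
  manifest <- list(seed = seed,
                   config_hash = config_hash(summaries),
                   provenance = as.list(provenance),
                   n_summaries = length(summaries))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, mf))
}

#' Model-outcome uncertainty from bootstrap percentile relative risks
#'
#' Summarises the bootstrap distribution of the composite relative risks and
#' reruns the full model at the 2.5th and 97.5th percentile relative risks
#' (rather than once per draw), returning the economic summaries at both
#' ends alongside the point estimate.
#'
#' @param bundle Parameter bundle with `$effects` risk-model specs.
#' @param n_draws Bootstrap draws.
#' @param seed RNG seed.
#' @return List with `point`, `lower` (2.5th percentile RRs) and `upper`
#'   (97.5th) `econ_summary` objects plus the percentile table.
#' @export
bootstrap_outcomes <- function(bundle, n_draws = 1000, seed = 1) {
  if (is.null(bundle$effects))
    stopf("bootstrap_outcomes: bundle carries no risk-model specs")
  q_dem <- bootstrap_composite_rr(bundle$effects$dementia, n_draws, seed)
  q_m <- bootstrap_composite_rr(bundle$effects$cvd, n_draws, seed + 1L, "male")
  q_f <- bootstrap_composite_rr(bundle$effects$cvd, n_draws, seed + 2L, "female")
  at <- function(p) {
    run_scenario(bundle, list(rr_overrides = list(
      dementia = q_dem[[p]],
      cvd = c(male = q_m[[p]], female = q_f[[p]]))))
  }
  list(point = run_scenario(bundle, list()),
       lower = at("p2.5"), upper = at("p97.5"),
       percentiles = rbind(dementia = q_dem, cvd_male = q_m, cvd_female = q_f))
}
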