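# Synthetic stand-ins, with documented statistical structure, for the input
# tables the published sources do not print: the life table, the starting
# cohort, the mortality-calibration prevalence table and the per-factor
# trial-effect table.  Every fixture satisfies the corresponding parameter
# type invariants and is flagged as fixture provenance in default_bundle().

#' Synthetic Gompertz life table
#'
#' All-cause mortality follows a Gompertz law `m(age) = alpha * exp(beta *
#' age)` for males, clipped to at most 1 per person-year; female rates are
#' the male rates divided by `sex_ratio`.  The fraction of deaths attributed
#' to CVD rises smoothly with age along a logistic curve.  When `target_e55`
#' is given, `alpha` is rescaled by numeric search so the female/male average
#' life expectancy at 55 matches the request.
#'
#' @param alpha Base male mortality rate at age 0 (Gompertz level), > 0.
#' @param beta Log-rate slope per year of age, >= 0.
#' @param sex_ratio Male/female rate ratio, > 0.
#' @param cvd_share_params List `lo`, `hi`, `mid`, `scale` for the logistic
#'   CVD death share.
#' @param ages Integer ages to tabulate.
#' @param target_e55 Optional life expectancy at age 55 (average of sexes) to
#'   match by rescaling `alpha`.
#' @return Life-table data frame (`age`, `sex`, `rate`, `cvd_fraction`).
#' @export
make_life_table <- function(alpha = 5.5e-6, beta = 0.114, sex_ratio = 1.6,
                            cvd_share_params = list(lo = 0.15, hi = 0.40,
                                                    mid = 80, scale = 12),
                            ages = 55:100, target_e55 = NULL) {
  if (alpha <= 0) stopf("make_life_table: alpha must be > 0")
  if (beta < 0) stopf("make_life_table: beta must be >= 0")
  build <- function(a) {
    male <- pmin(1, a * exp(beta * ages))
    female <- pmin(1, male / sex_ratio)
    p <- cvd_share_params
    share <- p$lo + (p$hi - p$lo) * stats::plogis((ages - p$mid) / p$scale)
    data.frame(
      age = rep(ages, 2),
      sex = rep(c("male", "female"), each = length(ages)),
      rate = c(male, female),
      cvd_fraction = rep(share, 2)
    )
  }
  if (!is.null(target_e55)) {
    obj <- function(log_a) {
      lt <- build(exp(log_a))
      mean(c(life_expectancy(lt, 55, "male"),
             life_expectancy(lt, 55, "female"))) - target_e55
    }
    root <- stats::uniroot(obj, log(alpha) + c(-8, 8), tol = 1e-10)
    alpha <- exp(root$root)
  }
  check_life_table(build(alpha))
}

#' Remaining life expectancy implied by a life table
#'
#' Discrete integration of the survival curve: half a year for the year of
#' death plus the sum of annual survival probabilities, truncated at the end
#' of the table.
#'
#' @param life_table Life-table data frame.
#' @param age Starting age.
#' @param sex `"male"` or `"female"`.
#' @return Expected remaining years.
#' @export
life_expectancy <- function(life_table, age, sex) {
  sub <- life_table[life_table$sex == sex & life_table$age >= age, ]
  sub <- sub[order(sub$age), ]
  q <- 1 - exp(-sub$rate)
  surv <- cumprod(1 - q)
  0.5 + sum(surv)
}

#' Synthetic starting-cohort distribution
#'
#' Cell proportions over 4 five-year age bands (55-59 ... 70-74), two sexes
#' and the four MI/stroke history combinations, assuming independence of MI
#' and stroke history within a cell.  No cell carries dementia history.
#'
#' @param band_weights Non-negative weights for the four age bands
#'   (normalised internally).
#' @param sex_split Proportion male.
#' @param mi_prev,stroke_prev History prevalence applied within every cell.
#' @param cohort_size Scaling count for event reporting.
#' @param jitter Standard deviation of optional multiplicative log-normal
#'   noise on the band weights (0 = deterministic).
#' @param seed RNG seed, used only when `jitter > 0`.
#' @return Validated starting-cohort list (`cells`, `cohort_size`).
#' @export
make_starting_cohort <- function(band_weights = c(0.35, 0.30, 0.20, 0.15),
                                 sex_split = 0.40, mi_prev = 0.06,
                                 stroke_prev = 0.05, cohort_size = 1e5,
                                 jitter = 0, seed = NULL) {
  if (any(band_weights < 0)) stopf("make_starting_cohort: negative band weight")
  if (jitter > 0)
    band_weights <- withr_seed(seed %||% 1L,
      band_weights * exp(stats::rnorm(length(band_weights), 0, jitter)))
  band_weights <- band_weights / sum(band_weights)
  lows <- c(55L, 60L, 65L, 70L)
  grid <- expand.grid(band = 1:4, sex = c("male", "female"),
                      mi_history = c(FALSE, TRUE),
                      stroke_history = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  p_sex <- ifelse(grid$sex == "male", sex_split, 1 - sex_split)
  p_mi <- ifelse(grid$mi_history, mi_prev, 1 - mi_prev)
  p_str <- ifelse(grid$stroke_history, stroke_prev, 1 - stroke_prev)
  cells <- data.frame(
    age_low = lows[grid$band], age_high = lows[grid$band] + 4L,
    sex = grid$sex, mi_history = grid$mi_history,
    stroke_history = grid$stroke_history,
    proportion = band_weights[grid$band] * p_sex * p_mi * p_str
  )
  check_cohort(list(cells = cells, cohort_size = cohort_size))
}

#' Model-consistent prevalence table
#'
#' Generates the disease prevalence used for mortality calibration by running
#' the state-transition engine itself from a disease-free cohort at
#' `start_age` with the given incidence and mortality inputs, and reading
#' age-specific marginal state occupancy among the living.  The circularity
#' (calibration needs prevalence, prevalence comes from a calibrated run) is
#' resolved by fixed-point iteration starting from zero prevalence.
#'
#' @param incidence Named list of incidence models (dementia, mi, stroke).
#' @param life_table Life-table data frame covering `start_age` onwards.
#' @param rrs Mortality relative risks (`cvd`, `other`).
#' @param start_age Disease-free start age of the internal run.
#' @param n_iter Fixed-point iterations (2 suffices in practice).
#' @return Prevalence data frame (`age`, `sex`, `disease`, `prevalence`).
#' @export
make_prevalence_table <- function(incidence, life_table, rrs,
                                  start_age = min(life_table$age),
                                  n_iter = 2) {
  ages <- seq(start_age, max(life_table$age))
  sim_ages <- ages[-length(ages)]
  prev <- data.frame(age = integer(0), sex = character(0),
                     disease = character(0), prevalence = numeric(0))
  has <- sapply(DISEASES, function(d) vapply(STATE_MASKS, mask_has, TRUE, d))
  for (it in seq_len(n_iter)) {
    rows <- list()
    for (sex in SEXES) {
      haz <- precompute_hazards(incidence, life_table, prev, rrs, sex, sim_ages)
      sim <- simulate_stratum(haz, start_age, 0L, length(sim_ages),
                              function(t) c(1, 1, 1))
      for (k in seq_along(ages)) {
        a <- ages[k]
        occ <- sim$occ[k, 1:8]    # occupancy at attained age a
        alive <- sum(occ)
        for (d in DISEASES) {
          p <- if (alive > 0) sum(occ[has[, d]]) / alive else 0
          rows[[length(rows) + 1]] <- data.frame(
            age = a, sex = sex, disease = d, prevalence = p)
        }
      }
    }
    prev <- do.call(rbind, rows)
  }
  check_prevalence(prev)
}

#' Synthetic trial-effect table
#'
#' Five modifiable factors — blood pressure/hypertension, body-mass
#' index/obesity, cholesterol, physical inactivity and smoking — with
#' per-unit relative risks in the range of published dementia (CAIDE-style)
#' and cardiovascular (QRISK-style) risk scores, and trial mean changes
#' calibrated in closed form so the composite relative risks equal 0.924 for
#' dementia and 0.982 (male) / 0.980 (female) for MI and stroke.  The
#' hypertension entry is fixed at relative risk 2.1 with a prevalence change
#' of -0.011 and the blood-pressure entry at 1.005 per mmHg (female) with a
#' change of -0.8 mmHg, the two published worked examples.  Standard errors
#' are scaled so the bootstrap interval width of the composites is of the
#' published order.
#'
#' @param rr_dementia,rr_cvd_male,rr_cvd_female Target composite relative
#'   risks the calibration reproduces exactly.
#' @return Named list of two [risk_model()] specs: `dementia` and `cvd`.
#' @export
make_trial_effect_table <- function(rr_dementia = 0.924, rr_cvd_male = 0.982,
                                    rr_cvd_female = 0.980) {
  # --- dementia spec (binary factors, prevalence-proportion deltas) ---
  dem <- data.frame(
    name = c("hypertension", "obesity", "high_cholesterol",
             "physical_inactivity", "smoking"),
    rr = c(2.1, 2.17, 1.89, 1.5, 1.26),
    delta0 = c(-0.011, -0.0271, -0.0181, -0.0904, -0.0090)
  )
  fixed <- dem$delta0[1] * log(dem$rr[1])
  s <- (log(rr_dementia) - fixed) / sum(dem$delta0[-1] * log(dem$rr[-1]))
  dem$delta <- c(dem$delta0[1], dem$delta0[-1] * s)
  sd_target_dem <- (log(1.108) - log(0.768)) / (2 * 1.96)
  cc <- sd_target_dem / sqrt(sum((dem$delta * log(dem$rr))^2))
  dem$se <- cc * abs(dem$delta)
  spec_dem <- risk_model("dementia", lapply(seq_len(nrow(dem)), function(i)
    risk_factor(dem$name[i], dem$rr[i], dem$delta[i], dem$se[i],
                "proportion")), label = "synthetic-CAIDE-like")

  # --- CVD spec (sex-specific per-unit relative risks) ---
  # female log-RRs are a fixed multiple k of male log-RRs, so calibrating the
  # male composite to rr_cvd_male makes the female one rr_cvd_male^k =
  # rr_cvd_female exactly
  k <- log(rr_cvd_female) / log(rr_cvd_male)
  cvd <- data.frame(
    name = c("sbp", "bmi", "cholesterol", "physical_inactivity", "smoking"),
    rr_f = c(1.005, NA, NA, NA, NA),
    rr_m = c(NA, 1.0204, 1.15, 1.12, 1.65),
    delta0 = c(-0.8, -0.15, -0.05, -0.0904, -0.0090),
    unit = c("mmHg", "kg/m^2", "mmol/L", "proportion", "proportion")
  )
  cvd$rr_m[1] <- exp(log(cvd$rr_f[1]) / k)
  cvd$rr_f[-1] <- exp(k * log(cvd$rr_m[-1]))
  fixed <- cvd$delta0[1] * log(cvd$rr_m[1])
  s <- (log(rr_cvd_male) - fixed) / sum(cvd$delta0[-1] * log(cvd$rr_m[-1]))
  cvd$delta <- c(cvd$delta0[1], cvd$delta0[-1] * s)
  sd_target_cvd <- (log(1.018) - log(0.946)) / (2 * 1.96)
  cc <- sd_target_cvd / sqrt(sum((cvd$delta * log(cvd$rr_m))^2))
  cvd$se <- cc * abs(cvd$delta)
  spec_cvd <- risk_model("cvd", lapply(seq_len(nrow(cvd)), function(i)
    risk_factor(cvd$name[i],
                c(male = cvd$rr_m[i], female = cvd$rr_f[i]),
                cvd$delta[i], cvd$se[i], cvd$unit[i])),
    label = "synthetic-QRISK-like")

  list(dementia = spec_dem, cvd = spec_cvd)
}
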