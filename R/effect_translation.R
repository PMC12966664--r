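# Translate trial risk-factor changes into per-disease relative risks,
# apply adherence-based waning, and quantify uncertainty by bootstrap.

factor_rr <- function(f, sex) {
  if (length(f$rr_per_unit) == 1) unname(f$rr_per_unit)
  else unname(f$rr_per_unit[[sex]])
}

#' Composite relative risk of a risk-model specification
#'
#' Multiplies the per-factor contributions `rr_per_unit ^ delta` over all
#' factors of the model: a factor with per-unit relative risk \eqn{r} whose
#' level changes by \eqn{\delta} contributes \eqn{r^\delta}, and independent
#' factor effects combine multiplicatively.  For example, a binary factor with
#' relative risk 2.1 whose prevalence falls by 1.1 percentage points
#' contributes \eqn{2.1^{-0.011} = 0.992}.
#'
#' @param spec A [risk_model()] specification.
#' @param sex `"male"` or `"female"`; used only for factors carrying
#'   sex-specific per-unit relative risks.
#' @param deltas Optional numeric vector overriding the factors' `delta`
#'   values (same order as `spec$factors`); used by the bootstrap.
#' @return A single positive relative risk.
#' @export
composite_relative_risk <- function(spec, sex = "female", deltas = NULL) {
  if (!length(spec$factors)) stopf("composite_relative_risk: empty spec")
  if (is.null(deltas)) deltas <- vapply(spec$factors, `[[`, 0, "delta")
  rrs <- vapply(spec$factors, factor_rr, 0, sex = sex)
  if (any(rrs <= 0)) stopf("composite_relative_risk: non-positive rr_per_unit")
  exp(sum(deltas * log(rrs)))
}

#' Effective relative risk after waning
#'
#' The intervention effect wanes as participants quit: in cycle `t`
#' (0-indexed from model start) the relative risk is the base relative risk
#' raised to the adherent fraction \eqn{(1-q)^t}.  After `duration_years` the
#' effect either vanishes (`post_duration_effect = "none"`) or is frozen at
#' its last within-duration value.
#'
#' @param base_rr Unitless relative risk at full adherence.
#' @param t Integer cycle index (years since model start), `>= 0`; vectorised.
#' @param policy A [waning_policy()].
#' @return Relative risk(s) in cycle `t`.
#' @export
effective_rr <- function(base_rr, t, policy) {
  if (any(t < 0)) stopf("effective_rr: t must be >= 0")
  q <- policy$annual_nonadherence
  out <- base_rr ^ ((1 - q) ^ t)
  after <- t >= policy$duration_years
  if (any(after)) {
    out[after] <- if (policy$post_duration_effect == "none") 1
    else base_rr ^ ((1 - q) ^ (policy$duration_years - 1))
  }
  out
}

#' Fraction of the cohort still adherent to the intervention
#'
#' `(1 - annual_nonadherence)^t` while the intervention runs and 0 from
#' `duration_years` onwards.  Intervention costs are scaled by this fraction:
#' no costs accrue for those who quit.
#'
#' @inheritParams effective_rr
#' @return Proportion(s) in \[0, 1\].
#' @export
adherent_fraction <- function(t, policy) {
  if (any(t < 0)) stopf("adherent_fraction: t must be >= 0")
  out <- (1 - policy$annual_nonadherence) ^ t
  out[t >= policy$duration_years] <- 0
  out
}

#' Bootstrap percentile interval for a composite relative risk
#'
#' Draws each factor's `delta` independently from a normal distribution with
#' mean `delta` and standard deviation `se_delta`, recomputes the composite
#' relative risk per draw, and summarises the draws by the 2.5th, 50th and
#' 97.5th percentiles.  Identical seeds give identical output.
#'
#' @inheritParams composite_relative_risk
#' @param n_draws Number of bootstrap draws (`>= 2`).
#' @param seed Integer RNG seed.
#' @return Named vector `c(p2.5 = , p50 = , p97.5 = )`.
#' @export
bootstrap_composite_rr <- function(spec, n_draws, seed, sex = "female") {
  if (n_draws < 2) stopf("bootstrap_composite_rr: n_draws must be >= 2")
  se <- vapply(spec$factors, function(f) {
    if (is.null(f$se_delta)) stopf("bootstrap_composite_rr: factor '%s' has no se_delta", f$name)
    f$se_delta
  }, 0)
  mu <- vapply(spec$factors, `[[`, 0, "delta")
  lrr <- log(vapply(spec$factors, factor_rr, 0, sex = sex))
  draws <- withr_seed(seed, {
    d <- matrix(stats::rnorm(n_draws * length(mu), mean = mu, sd = se),
                nrow = n_draws, byrow = TRUE)
    exp(d %*% lrr)
  })
  q <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  c(p2.5 = q[1], p50 = q[2], p97.5 = q[3])
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}
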