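---
title: "Methods: a dementia–cardiovascular multimorbidity cohort model for cost-utility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dementia–cardiovascular multimorbidity cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demcvd)
```

## Scope and rationale

`demcvd` implements a deterministic cohort state-transition model for
evaluating preventive interventions that act on modifiable risk factors
shared by dementia and cardiovascular disease.  Dementia-only decision
models miss the spill-over of risk-factor improvement onto myocardial
infarction (MI) and stroke; full general-health microsimulations are hard to
parameterise for two country settings.  The middle ground taken here is a
nine-state multimorbidity Markov model over the subsets of
{dementia, MI, stroke} plus death, run yearly from a mixed-age starting
cohort to a maximum age (default 100).

Two strong assumptions are inherited from the evidence base and should be
kept in mind when interpreting any output: (i) causality — changing a risk
factor is assumed to change disease incidence according to the risk score's
per-unit relative risk; (ii) persistence — the trial effect is assumed to
persist, attenuated only by the adherence model below.

## Effect translation and waning

Each risk factor carries a per-unit relative risk $r_k$ (optionally
sex-specific) and a trial mean change $\delta_k$.  The composite relative
risk per disease is the product $\prod_k r_k^{\delta_k}$
(`composite_relative_risk()`).  Binary factors express $\delta_k$ as a
change in prevalence proportion; continuous factors use natural units.
This convention reproduces the two published worked examples embedded in the
bundled factor table: $2.1^{-0.011} = 0.992$ for hypertension, and a
1.005/mmHg blood-pressure relative risk with a −0.8 mmHg change.  We note
that $1.005^{-0.8} = 0.9960$, while the source text quotes 0.997 for this
example; the package does not force agreement and keeps the stated formula.

Waning (`effective_rr()`): in cycle $t$ (0-indexed) the applied relative
risk is $RR^{(1-q)^t}$ with annual non-adherence $q$ (default 0.10) for
$t$ below the intervention duration (default 10 years).  Afterwards the
effect is removed (`post_duration_effect = "none"`, the default) or frozen
at its last within-duration value.  The adherent fraction $(1-q)^t$
(`adherent_fraction()`) also scales intervention costs — those who quit pay
nothing further.

Uncertainty (`bootstrap_composite_rr()`): factor changes are drawn
independently from $N(\delta_k, se_k^2)$ (no correlation matrix is
available; a user-supplied spec can encode one implicitly by transforming
factors) and the composite is summarised by its 2.5th/50th/97.5th
percentiles.  Model-outcome intervals (`bootstrap_outcomes()`) rerun the
full model only at the percentile relative risks rather than once per draw;
this was an open design choice and the cheaper option matches how such
intervals are usually reported for deterministic models.

## Incidence and mortality

Incidence is log-linear in age and sex on the rate scale:
$\exp(\beta_0 + \beta_a \, a + \beta_s \, male)$, times history relative
risks for diseases already present, times the intervention relative risk.
A log link (rather than logistic) was chosen because the transcribed
coefficients then give epidemiologically plausible annual dementia
incidence (about 1 % at age 70 and 2.7 % at 80 for UK males).  Sex is coded
male = 1 everywhere, matching the explicit `*male` term of the utility
regression; the interaction term named in the source inputs has no
published coefficient and defaults to 0 (`b_age_sex` accepts one).
"Not included" history relative risks are exactly 1.  Dementia history is
absorbing (no repeat onsets); MI and stroke recur through their own history
relative risks, and recurrences count as events without changing state.

Mortality calibration (`calibrate_baseline_mortality()`): the life-table
all-cause rate is split into CVD and other causes by the CVD death
fraction, and each cause rate is divided by the prevalence-weighted mean
mortality relative risk $\sum_s \pi_s RR_s$ over the eight history states,
where joint prevalence $\pi_s$ assumes independence of the three marginal
prevalences and a combination state's relative risk is the product of its
single-disease relative risks.  The joint form was chosen (over sequential
per-disease calibration, which the available description leaves open)
because it makes the round-trip exact: recombining the calibrated
state-specific rates with the same weights returns the life-table cause
rate to machine precision, which the test suite asserts at `1e-12`.

## The transition engine

Cycle length is 12 months.  Within a cycle, death is resolved first from
the summed cause-specific rates (cause attribution proportional to the two
rates); conditional on survival each absent disease onsets independently
with probability $1 - e^{-rate}$, so simultaneous multi-disease onset is
permitted — the combination states need a path and independence is the
neutral assumption.  Age bands in the starting cohort expand to integer
ages with uniform weights; each stratum ages one year per cycle and no
stratum carries dementia history at baseline.

Accounting conventions: state membership is counted at end-of-cycle
occupancy; events accrue in the cycle they occur; there is no half-cycle
correction (none is described for the original analysis); discounting uses
$(1+r)^{-t}$ with $t = 0$ for the first cycle.  Intervention costs use
start-of-cycle survivors (people pay for the year they enter), which also
makes the coaching total equal the closed-form annuity
$price \times \sum_t (1-q)^t (1+r)^{-t} S(t)$ checked in the tests.

The primary correctness oracle is stochastic: a seeded walker
microsimulation of the same per-cycle process must match the deterministic
transition distribution within three Monte-Carlo standard errors, and with
MI and stroke switched off the nine-state engine must equal an independent
three-state (at-risk/dementia/death) reference exactly.

## Economics

Utilities: a quadratic general-population regression in age with a male
shift, multiplied by disease utility ratios.  Multimorbidity combines
multiplicatively by default — ratios compound, which keeps utilities
positive and matches how the single-disease ratios were derived relative to
the general population; an additive-decrement switch exists because the
literature is genuinely split.  MI and stroke events add a one-off
event-year disutility.  Costs: per-disease annual post-year-1 costs by
payer (health sector, informal care) on history person-time, plus one-off
year-1 additional costs per event ("additional" meaning on top of the
annual cost in the event cycle).  Platform costs are adherence-weighted
like coaching.

`economic_summary()` reports ICER $= \Delta C / \Delta E$ (flagged
undefined when $\Delta E = 0$) and iNHB
$= \Delta E - \Delta C / \lambda$.  `headroom_cost()` solves for the
per-user-year intervention price at which iNHB $= 0$ by bisection to a
$10^{-6}$ relative tolerance; because iNHB is linear in the price the
closed form $(\lambda \Delta E - \Delta C_{disease}) / A$, with $A$ the
discounted adherence-weighted survivor annuity, must agree, and the tests
require it.  Its `effect_scope = "dementia_only"` removes only the CVD
*effect* (the pricing question "what is the dementia benefit worth"),
whereas the scenario knob `dementia_only` removes MI and stroke from the
model entirely (a dementia-only model), so MI/stroke differences are
exactly zero there.

## Synthetic fixtures

Four inputs of the original analysis are not published and are emulated by
seeded, deterministic generators, flagged `"fixture"` in
`bundle$provenance` so reports can separate transcribed from emulated
inputs:

* `make_life_table()` — Gompertz mortality $\alpha e^{\beta a}$ (no Makeham
  term; over ages 55–100 the background constant is negligible), a
  male/female rate ratio, and a logistic CVD death share rising with age.
  UK defaults ($\alpha = 5.5\times10^{-6}$, $\beta = 0.114$, ratio 1.6)
  were set from typical ONS-order magnitudes (male $q_{70} \approx 0.016$,
  $q_{80} \approx 0.05$), giving $e_{55} \approx 26$–29 years; China uses a
  slightly heavier schedule.  An optional numeric search rescales $\alpha$
  to a requested life expectancy at 55.
* `make_starting_cohort()` — four 5-year age bands (55–74) × sex × MI/stroke
  history with independent history prevalence within cells; defaults
  (40 % male, band weights 0.35/0.30/0.20/0.15, MI 6 %, stroke 5 %) reflect
  a community prevention-trial population skewed toward the younger bands.
* `make_prevalence_table()` — generated by the engine itself from a
  disease-free cohort at age 40, which guarantees internal consistency
  between fixture incidence, mortality and prevalence; the circular
  dependence on calibration is resolved by fixed-point iteration from zero
  prevalence (two passes change prevalences by well under the calibration
  tolerance that matters).
* `make_trial_effect_table()` — five factors with per-unit relative risks
  in the range of published dementia and cardiovascular risk scores.  Trial
  changes are calibrated in closed form (a single exponent scaling, which
  is exact because the composite is a power function of the deltas) so the
  composites equal 0.924 (dementia) and 0.982/0.980 (male/female CVD)
  exactly, while the two published worked-example entries are held fixed.
  Female CVD log-relative-risks are a fixed multiple of the male ones so
  both sexes calibrate simultaneously.  Standard errors are scaled so the
  bootstrap interval widths are of the published order.

What passing tests therefore show: the pipeline's structure, calibration,
conservation and economic arithmetic are correct under realistic inputs.
What they do not show: agreement of absolute base-case outcome levels with
any published table — those depend on the unpublished life tables,
prevalence and baseline distributions, and the fixtures make no claim to
match real ONS or China yearbook mortality beyond shape and life-expectancy
order.

## Scenarios, validation and reporting

`run_scenario()` applies pure overrides (the base bundle is never mutated):
start age/sex strata, horizon (80/90/100), discount rate (1 %/7 %),
willingness to pay, intervention-cost multipliers (×1/3, ×3), lifetime full
adherence with or without repeated coaching, a dementia-only model, a
no-CVD-history start, direct relative-risk overrides and an incidence
uplift.  Scenarios that would need unpublished subgroup effect estimates
(country-specific or adherent-subgroup effects, alternative risk-score
coefficient tables) are supported only through user-supplied override
values — there is deliberately no bundled descriptor that would fabricate
them.

`validate_prevalence()` classifies simulated prevalence against observed
confidence intervals: `good` inside the interval (bounds inclusive),
`moderate` outside by at most one interval half-width beyond the violated
bound — the chosen reading of "not more than two times beyond the observed
confidence interval", which is ambiguous as phrased — and `poor` beyond
that.

`write_report()` emits two-strategy outcome tables with difference and
percent-difference columns, a combined scenario table, and a JSON manifest
(seed, configuration hash, provenance flags); identical inputs give
byte-identical files.

## Numerical choices and problem sizes

Rates convert to probabilities as $1 - e^{-rate}$; zero total mortality
defines a zero cause split; utilities clamp to $[0,1]$; occupancy
conservation holds to $10^{-10}$ per cycle and calibration round-trips to
$10^{-12}$.  The test suite exercises 1,000 randomised single-stratum
bundles for conservation, a $10^6$-walker microsimulation check, $10^5$
bootstrap draws against the log-normal closed form, and full base-case
runs for both countries; the whole suite completes in well under five
minutes on a single core, and `scripts/acceptance.R` in under a minute.

## Known limitations

Only three diseases are modelled; costs in life-years gained from
unmodelled diseases are excluded, informal stroke costs are not adjusted
for attribution, and no probabilistic sensitivity analysis is offered (the
dominant uncertainties — causality and sustained adherence — have no
defensible distributions, and a probabilistic analysis omitting them would
misrepresent uncertainty).  The bootstrap treats factor effects as
independent normals.  Currencies are never converted; each bundle is
self-contained at 2021 price level.
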