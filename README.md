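# demcvd

A cohort state-transition (Markov) model of dementia, myocardial infarction
(MI) and stroke for health-economic evaluation of preventive risk-factor
interventions, with bundled UK and China parameter settings.

The package is aimed at health economists and epidemiologists who want to
extrapolate a short-term trial effect on modifiable risk factors (blood
pressure, body-mass index, cholesterol, physical inactivity, smoking) into
lifetime disease events, quality-adjusted life years (QALYs), costs, an
incremental cost-effectiveness ratio (ICER) and incremental net health
benefit (iNHB), including scenario analyses, bootstrap uncertainty intervals
and headroom pricing.

## The model

**Effect translation.** A trial change `δ_k` in risk factor `k`, combined
with that factor's per-unit relative risk `r_k` from a published risk score
(CAIDE-style for dementia, QRISK-style for cardiovascular disease), yields a
composite per-disease relative risk

    RR = ∏_k r_k^{δ_k}

For example a 1.1 percentage-point fall in hypertension prevalence with a
per-unit relative risk of 2.1 contributes `2.1^(-0.011) = 0.992`.  The
effect wanes with adherence: in model year `t` the applied relative risk is
`RR^{(1-q)^t}` for an annual non-adherence rate `q` (default 10 %/year) up
to a maximum duration (default 10 years), after which it vanishes.

**Disease and death.** Eight alive states (every subset of
{dementia, MI, stroke}) plus death.  Incidence is log-linear in age and sex
with history relative risks (dementia history is absorbing; MI and stroke
recur via their own history relative risks).  Disease-free mortality is
calibrated from a general-population life table: the all-cause rate is split
into CVD/other causes and divided by the prevalence-weighted mean mortality
relative risk over the eight states, so that recombining the state-specific
rates reproduces the life table exactly.  Transitions to death are handled
first each yearly cycle; conditional on survival, absent diseases onset
independently.

**Economics.** Person-time in each state accrues state utility
(a quadratic general-population regression times multiplicative disease
ratios) and annual disease costs by payer (health sector, informal care);
each event adds a one-off year-1 cost and an event-year disutility.
Intervention platform and coaching prices accrue per adherent survivor.
With discounted totals `E` (QALYs) and `C` (costs) per strategy,

    ICER = (C_i - C_c) / (E_i - E_c)
    iNHB = (E_i - E_c) - (C_i - C_c) / λ

for willingness to pay `λ` (£20,000/QALY UK; ¥81,419/QALY China).

**Inputs.** Published scalar inputs (regression coefficients, relative
risks, utilities, costs, discount rates) are transcribed into
`default_bundle()`.  The tables that are not published — life tables, the
calibration prevalence table, the starting-cohort distribution and the
per-factor trial-effect table — are generated by documented synthetic
fixtures (`make_life_table()`, `make_starting_cohort()`,
`make_prevalence_table()`, `make_trial_effect_table()`) and flagged as
`"fixture"` in `bundle$provenance`, so absolute outcome levels under the
defaults are illustrative, not reproductions of any published table.

## Worked example

```r
library(demcvd)

b   <- default_bundle("uk")
soc <- run_cohort(b, "standard_of_care")
int <- run_cohort(b, "intervention")
economic_summary(b, soc, int)
```

```
Economic summary (uk, cohort 100,000)
                 dementia    mi stroke
standard of care    58368 27746  19738
intervention        58208 27678  19678
prevented             159    68     60
QALYs/person: 12.0377 vs 12.0535 (delta +0.01575)
Costs/person: 47462 vs 51554 (delta +4092)
ICER: 259871   iNHB: -0.1888 (wtp 20000)
```

Reading: under the synthetic UK inputs the intervention prevents 159
dementia onsets, 68 MI and 60 stroke events per 100,000 people, gains
0.0157 discounted QALYs per person, and costs £4,092 more per person
(mostly coaching), giving an ICER of about £260,000/QALY — far above the
£20,000 threshold, hence the negative incremental net health benefit of
-0.19 QALYs per person.

Scenario and headroom analyses:

```r
run_scenario(b, list(cost_multiplier = 3))         # tripled intervention cost
run_scenario(b, list(lifetime_full_adherence = TRUE))
headroom_cost(b, "dementia_only")$cost             # break-even annual price
```

A thin command-line interface is installed as `exec/demcvd` with subcommands
`run`, `scenario`, `validate`, `fixtures`, `translate` and `headroom`.

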