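Package: demcvd
Title: Cohort State-Transition Modelling of Dementia and Cardiovascular
    Multimorbidity for Cost-Utility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic cohort state-transition (Markov) model of
    dementia, myocardial infarction and stroke for health-economic
    evaluation of risk-factor interventions.  Trial effects on modifiable
    risk factors (blood pressure, body-mass index, cholesterol, physical
    inactivity, smoking) are translated into per-disease relative risks
    via published risk-score coefficients, attenuated over time by an
    adherence-based waning schedule, and propagated through a nine-state
    multimorbidity model with life-table-calibrated cause-specific
    mortality.  Outputs include disease events, person-years, discounted
    quality-adjusted life years and costs, incremental cost-effectiveness
    ratios, incremental net health benefit, bootstrap uncertainty
    intervals, scenario analyses and headroom pricing for UK and China
    parameter sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
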