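Package: pdtrials
Title: Simulation and Estimation for Prediction-Driven Randomized Trials in
    Comparative Effectiveness Settings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating confirmatory prediction-driven
    randomized controlled trials that compare approved treatment options using a
    predictive biomarker. Implements four trial designs (enrichment,
    biomarker-stratified, biomarker-strategy and modified biomarker-strategy),
    patient-level survival data generation with physician-choice behaviour and
    administrative censoring, and estimation of three contrasts (subgroup
    treatment effect, differential treatment effect, and clinical utility in
    comparative and experimental forms) via the logrank test, Cox proportional
    hazards regression, and jackknife pseudo-observation regression for survival
    probability and restricted mean survival time differences. A Monte-Carlo
    engine computes operating characteristics (type I error, power, mean
    estimate) for design and estimator choices.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
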