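Package: smanbs
Title: Cost-Utility Modelling of Newborn Screening for Spinal Muscular
    Atrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic modelling of population newborn screening
    for spinal muscular atrophy (SMA): a screening decision tree feeding a
    six-state Markov cohort model driven by age-dependent transition-rate
    matrices and their matrix exponentials, parametric survival fitting of
    milestone-achievement and mortality data with corrected-AIC model
    selection, treatment-cost schedules for disease-modifying therapies,
    discounted cost and QALY accounting, and probabilistic and
    deterministic sensitivity analysis with net-monetary-benefit and
    cost-effectiveness acceptability summaries.  A synthetic-data
    subsystem generates event-time datasets and life tables with known
    ground-truth hazards so every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    survival,
    withr,
    optparse
Config/testthat/edition: 3
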