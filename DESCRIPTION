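Package: shockindex
Title: Shock Index Thresholds for Adverse Maternal Outcomes in
    Hypovolemic Shock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating vital-sign predictors of adverse maternal
    outcomes in women with hypovolemic shock secondary to obstetric
    hemorrhage. Computes derived hemodynamic indices (shock index, mean
    arterial pressure, pulse pressure) at the worst measurement point of a
    patient's first-hour vital-sign series, builds WHO near-miss style
    composite outcomes, estimates nonparametric ROC curves with DeLong
    variances and paired AUC-equality tests, reports threshold operating
    characteristics (sensitivity, specificity, predictive values) with exact
    Clopper-Pearson intervals, derives predictor values at given specificity
    centiles with distribution-free confidence intervals, and simulates
    seeded synthetic cohorts with the statistical structure the analysis
    assumes so the whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
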