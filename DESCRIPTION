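Package: garvanval
Title: Absolute Fracture-Risk Prediction and External-Validation Toolkit
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements sex-specific absolute fracture-risk models of the
    Garvan nomogram family (5- and 10-year hip and non-vertebral
    osteoporotic fracture risk, with bone-mineral-density and body-weight
    variants) together with a complete external-validation pipeline:
    cohort input/output with person-year incidence rates, ROC/AUC
    discrimination with paired DeLong comparison, quantile-group
    calibration against Kaplan-Meier observed risk, predicted-risk ratios,
    and categorical net reclassification improvement. A synthetic-cohort
    generator produces elderly cohorts with known ground truth (fracture
    times calibrated to the risk model's own predictions, competing
    mortality, administrative censoring) so every pipeline stage is
    testable without access to the original cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
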