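Package: sdbscreen
Title: Validation of Sleep-Disordered Breathing Screening Questionnaires in Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the Berlin Questionnaire and the Wilson Optimized Model on
    questionnaire data from pregnant cohorts and evaluates both screens against
    polysomnography-derived sleep-disordered breathing status at respiratory
    disturbance index (RDI) thresholds of 5 and 15 events per hour. Provides
    confusion-table diagnostics (sensitivity, specificity, predictive values,
    likelihood ratio), Pearson chi-square classifier comparisons, mother versus
    bedpartner agreement cross-tabulation, ROC curve and AUC analysis with
    DeLong confidence intervals and paired AUC tests, and a calibrated
    synthetic-cohort generator so the full pipeline can be exercised and tested
    without access to patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
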