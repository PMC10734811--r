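Package: pariscore
Title: Persistent AKI Risk Index Scoring and Diagnostic Accuracy for ICU Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the persistent acute kidney injury risk index (PARI) and
    its components from longitudinal ICU records, stages acute kidney injury by
    the KDIGO creatinine, urine-output and renal-replacement-therapy criteria,
    applies study-style cohort eligibility filters, derives renal and vital
    outcomes within 72 hours and 7 days, and evaluates predictor accuracy with
    empirical ROC curves, DeLong paired AUC comparisons, Youden-index cutoff
    selection, and fixed-cutoff 2x2 metrics with Wald confidence intervals.
    Includes a latent-class synthetic cohort generator so the full pipeline is
    testable without patient data, plus CSV/JSON report writers and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    withr
Config/testthat/edition: 3
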