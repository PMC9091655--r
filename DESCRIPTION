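Package: dcgrace
Title: Deceleration Capacity, Heart Rate Variability and Incremental
    Prognostic Value of Clinical Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes phase-rectified signal averaging (PRSA) deceleration
    capacity and a 24-hour heart rate variability panel (SDNN, SDANN, rMSSD,
    pNN50, Lomb-Scargle LF/HF band powers) from beat-to-beat RR interval
    recordings, stratifies patients into deceleration-capacity risk groups,
    and quantifies the incremental prognostic value of adding an autonomic
    marker to an established clinical risk score (such as the postdischarge
    GRACE score) via nested likelihood-ratio tests, small-sample corrected
    AIC with Akaike weights, category-free continuous net reclassification
    improvement, integrated discrimination improvement, and ROC analysis
    with DeLong standard errors. Includes Cox proportional-hazards and
    Kaplan-Meier survival modelling, a synthetic Holter-cohort generator
    with known ground truth for end-to-end validation, and a command-line
    pipeline that reproduces the full analysis from per-patient RR files
    and a cohort covariate table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
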