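Package: cytoROC
Title: Serum Biomarker Cutoffs and Combined Scores for Predicting
    Cytoreductive Surgery Outcome in Ovarian Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diagnostic-accuracy toolkit for predicting suboptimal versus
    optimal cytoreductive surgery in epithelial ovarian cancer from
    preoperative serum CA-125, FASN and GLS. Builds empirical ROC curves,
    selects Youden-optimal cutoff points, computes sensitivity,
    specificity, accuracy and predictive values from exact 2x2 counts,
    attaches Hanley-McNeil confidence intervals to the AUC, and constructs
    multiplicative dichotomized-combination scores from marker panels. A
    synthetic-cohort generator reproduces the two-group marker
    distributions of the motivating 109-patient study so the whole
    pipeline can be exercised, and published summary rates can be
    back-solved to integer confusion matrices for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
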