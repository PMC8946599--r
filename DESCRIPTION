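Package: seromiR
Title: Serum microRNA Diagnostic Signatures for Multi-Cancer Early Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates blood-based microRNA diagnostic models of
    the kind used for multi-cancer early detection (MCED) screening.  The
    pipeline covers microarray sample quality control (negative-control
    coefficient of variation and flagged-probe rules), presence calls,
    background subtraction, internal-control calibration, redundant-sample
    removal by pairwise correlation, empirical-Bayes moderated-t differential
    expression with Benjamini-Hochberg adjustment, panel-size selection by
    ten-fold cross-validated AUC, a weighted diagnostic index normalized to
    0-10 with a zero-false-positive cut-point, and screening-test operating
    characteristics (ROC/AUC with paired bootstrap comparison, McNemar tests,
    subgroup sensitivities, and positive predictive value).  A synthetic
    cohort generator emulating the serum miRNA microarray data structure
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
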