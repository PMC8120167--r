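Package: stromascope
Title: Computerized Tumor-Stromal Ratio Assessment and Prognostic Nomogram
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the tumor-stromal ratio (TSR) on cytokeratin
    (CK/DAB) immunostained tissue-microarray core images by a
    gradient-plus-morphology segmentation pipeline, and carries the
    marker through the full prognostic workflow used in breast-cancer
    TSR studies: best-P-value survival cutpoint search (X-tile style,
    with Miller-Siegmund correction), contingency-table association
    tests, Kaplan-Meier and log-rank machinery, Cox model fitting with
    enter/forward/backward selection, a points-based nomogram with
    concordance, calibration and ROC validation, and total-points risk
    stratification. Ships synthetic image and cohort generators with
    pixel-level ground truth so the whole chain is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    survival,
    pROC,
    jsonlite,
    png,
    tiff,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
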