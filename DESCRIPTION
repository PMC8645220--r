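Package: ppsepsis
Title: Validation of Community Health Worker Screening for Puerperal Sepsis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a community-health-worker diagnostic algorithm for
    postpartum (puerperal) sepsis and the statistical machinery used to
    validate it against physician assessment: Cohen's kappa and
    prevalence-adjusted bias-adjusted kappa (PABAK) with prevalence and bias
    indices and positive/negative agreement, sensitivity and specificity with
    exact binomial intervals, verification-bias (Begg-Greenes) adjustment for
    screen-dependent verification designs, ROC/AUROC for the screening
    classification, sample-size arithmetic for nested case-control validation
    studies, and a synthetic postpartum surveillance cohort generator with
    1:3 matched control sampling for end-to-end parameter-recovery checks.
    Ships the per-site 2x2 counts of a three-site validation study as a
    fixture and reproduces its agreement and validity tables with a
    cell-by-cell discrepancy report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC
Config/testthat/edition: 3
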