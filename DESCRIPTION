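Package: checkrisk
Title: Development and Validation of Weighted Clinical Risk Checklists
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating weighted dichotomous-item
    clinical risk checklists for rare prospective outcomes, modelled on the
    workflow used to develop suicide-attempt risk scores. Provides checklist
    scoring with risk bands and missing-as-absent handling, rank-based
    ROC/AUC with DeLong confidence intervals and paired AUC comparison,
    signal-detection cut-point tables with chance-corrected quality indices
    (quality of sensitivity, specificity, and efficiency),
    concentration-of-risk capture curves, logistic calibration with
    Nagelkerke pseudo R-squared, risk-group contingency analysis with risk
    and odds ratios, evidence-guided forward selection with weight doubling,
    and a calibrated generator of synthetic cohorts with correlated binary
    risk factors and a rare logistic outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pROC,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
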