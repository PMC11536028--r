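Package: ptau217
Title: Diagnostic Accuracy and PET-Based Staging Analysis for Plasma pTau217
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate a plasma pTau217 immunoassay against amyloid
    and tau PET: composite tau-PET regions of interest (Me, Te, R, MetaT,
    Braak I-VI), data-driven tau positivity thresholds (mean + k SD or
    percentile of the amyloid-negative cognitively unimpaired reference
    stratum), PET-based Braak staging with atypical-profile detection,
    biological Alzheimer's disease staging (Initial/Early/Intermediate/
    Advanced), and a diagnostic-accuracy suite with ROC/AUC, Youden and
    fixed-sensitivity/specificity operating points, two-threshold triage
    with an indeterminate zone, percentile-bootstrap confidence intervals,
    and DeLong comparisons of correlated AUCs. A calibrated synthetic
    cohort generator emulates the joint structure of a memory-clinic
    research cohort so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
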