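Package: fittriage
Title: FIT Threshold Optimisation for Capsule-Colonoscopy Triage in Iron
    Deficiency Anaemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for locating cost-effective faecal
    immunochemical test (FIT) triage thresholds in iron-deficiency-anaemia
    cohorts investigated for colorectal cancer. Ingests patient-level cohort
    tables with censored quantitative FIT results, derives the predicted
    colon-capsule-to-colonoscopy conversion (urgent) label from colonic
    findings, quantifies FIT's discriminative accuracy (ROC/AUC with DeLong
    intervals, univariate and multivariable logistic regression), and locates
    candidate thresholds by three complementary routes: a CUSUM cumulative
    count scan with jump-point detection, an incremental two-group
    significance scan, and decision-curve plus monetary cost-benefit
    analysis. A seeded synthetic-cohort generator reproduces the statistical
    structure of such cohorts so the whole pipeline is testable without
    patient data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
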