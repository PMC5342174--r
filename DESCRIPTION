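Package: acspredict
Title: Urinary Peptidome Analysis for Prognosis of Acute Coronary Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis workflow for prognostic classification of future
    acute coronary syndrome (ACS) events from capillary electrophoresis
    mass spectrometry (CE-MS) urinary peptide profiles. Covers migration-time
    calibration by locally weighted regression, housekeeping-peptide
    normalization of urine dilution, ppm-tolerance clustering of peak lists
    against a peptide catalogue, frequency-filtered Wilcoxon biomarker
    screening with Benjamini-Hochberg correction, support vector machine
    pattern scoring with a radial basis kernel, a linear composite risk
    score, and the prognostic evaluation toolkit: Youden-index thresholds
    with exact binomial confidence intervals, likelihood ratios, Harrell's
    concordance for censored outcomes, Kaplan-Meier and Cox analyses, and
    reclassification statistics (IDI/NRI). A synthetic-cohort generator
    reproduces the statistical structure the pipeline assumes so every
    stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC,
    withr
Config/testthat/edition: 3
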