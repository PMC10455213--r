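Package: amlrisk
Title: Chemosensitivity-Based Prognostic Risk Scale for Acute Myeloid Leukemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates a six-parameter prognostic scale for risk
    stratification of acute myeloid leukemia (AML) patients from ex vivo
    chemosensitivity of tumor cells (WST-1 dose-response viability and IC50),
    MDR1 mRNA relative expression (delta-delta-Ct fold change), tumor origin,
    unfavorable cytogenetics, age and aberrant immunophenotype. Provides
    raw-assay quantification (viability curves, log-logistic IC50 with
    right-censoring, qPCR fold change), per-patient scoring and risk-group
    assignment, and a full evaluation battery: Spearman correlation matrices
    with strength bands, Kaplan-Meier and log-rank survival comparison, ROC
    analysis with Hanley-McNeil standard errors and Youden-index cutoffs, and
    univariate and multivariate Cox proportional-hazards regression. A
    synthetic cohort generator with a latent resistance burden emulates the
    statistical structure of such a study population so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
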