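Package: prepbarriers
Title: Barriers to HIV Pre-Exposure Prophylaxis Uptake in MSM Survey Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for identifying barriers to HIV pre-exposure
    prophylaxis (PrEP) uptake among men who have sex with men (MSM) from
    categorical survey data. Implements guideline-based PrEP-indication
    eligibility classification and a participant-selection flow with an
    auditable ledger, derived-variable construction (square-root equivalised
    household income, HIV-specialist density bands), reference-coded
    one-hot design matrices with explicit missing-value handling,
    elastic-net logistic regression with repeated stratified
    cross-validation, a one-standard-error elbow rule and sparsity/AIC
    model choice, stratified bootstrap percentile confidence intervals and
    one-sided bootstrap p-values, and stratified contingency analyses of
    self-reported reasons for non-use with Benjamini-Hochberg correction
    and Wilson score intervals. A seeded synthetic-cohort generator
    emulates the statistical structure of such surveys so the whole
    pipeline is testable without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
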