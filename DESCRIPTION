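Package: braincca
Title: Canonical Correlation Pipelines for Multimodal Brain-Behavior Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multivariate association analysis between a multimodal
    imaging feature set and a behavioral feature set in a patient cohort with a
    matched healthy-control reference sample. Implements reference-cohort
    preprocessing (control-referenced z-standardization, winsorization,
    reverse-coding, group-wise regression imputation, control-fitted robust
    covariate residualization, hemisphere averaging, multivariate normality
    diagnostics), canonical correlation analysis from first principles with
    loadings, cross-loadings and Wilks' lambda sequential tests, permutation
    and k-fold cross-validation inference on the first canonical correlation,
    dual-regression resting-state network integrity and segregation metrics
    with motion-based exclusion, and a synthetic-cohort generator with planted
    canonical structure for ground-truth validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
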