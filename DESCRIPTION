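Package: stabmi
Title: Stable Prognostic Model Selection with Multiple Imputation and
    Bootstrapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and internally validating prognostic
    models for binary outcomes in cohorts with missing values. Implements
    multiple imputation by chained equations with predictive mean matching,
    backward-elimination logistic modelling with an inclusion-fraction rule
    for pooling variable selection across imputed data sets, a two-step
    bootstrap model-selection procedure that quantifies model stability as
    model-selection frequencies, and bootstrap optimism-corrected
    performance measures (c-index, calibration slope, Nagelkerke R
    squared). Includes a synthetic cohort generator with known truth and
    controllable MCAR/MAR missingness for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
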