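Package: stabclock
Title: Stability Selection and Nonlinear Epigenetic Clocks for Gestational Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compact epigenetic gestational-age clocks from DNA
    methylation beta values. Implements stability selection - repeated lasso
    on random half-subsamples - with a permutation-calibrated false-discovery
    bound that converts an expected-false-discovery budget into a
    selection-probability threshold, nested generalized additive model (GAM)
    clocks with effective-degrees-of-freedom nonlinearity diagnostics, robust
    evaluation (median absolute deviation in days, MM-type calibration
    regression), and a synthetic cord-blood cohort generator with planted
    linear and nonlinear methylation-gestational-age signal so the whole
    pipeline is testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    mgcv,
    MASS,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    patchwork
Config/testthat/edition: 3
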