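Package: jointirt
Title: Joint Item Response Models for Manual and Automatic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint item response models for manually and automatically scored
    open-ended test items. Implements the constant-error-rate (CER) and
    variable-error-rate (VER) models for classifier error, the marginal
    four-parameter logistic (4PL) and generalized 4PL (G4PL) measurement
    models that allow ability estimation from automatic scores alone,
    expected a posteriori (EAP) ability estimation by rectangle-rule
    quadrature, Kolmogorov-Smirnov diagnostics for the conditional
    independence of classification errors and ability, and a Monte-Carlo
    simulation framework for parameter recovery under calibrated classifier
    error-rate distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
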