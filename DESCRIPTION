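Package: jointvar
Title: Robust Tests of Mean and Variance Effects for Continuous Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Location (mean), scale (variance) and joint location-and-scale
    tests for continuous outcomes against binary, categorical or continuous
    exposures. Implements the classic Brown-Forsythe test, its regression
    reformulation via least absolute deviation residuals (valid for
    continuous exposures), Bartlett's test, a Fisher-combination joint test
    (JLSp) and a joint location-and-scale score test (JLSsc) with a
    chi-squared reference distribution. Includes outcome transformations
    (M-value, inverse-normal rank), outlier handling, simulation engines for
    type-I-error and power studies on methylation-like data, and a
    feature-by-sample scan interface for epigenome-wide analyses of
    differential mean and variability.
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
    utils
Suggests:
    car,
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
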