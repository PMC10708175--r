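Package: ozonebw
Title: Maternal Ozone Exposure and Birthweight: Fixed-Effects Association,
    Nonlinear Exposure-Response, and Attributable Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the effect of maternal peak-season ozone
    exposure on birthweight from stratified household-survey microdata.
    Implements the WHO peak-season and gestational exposure metrics from
    monthly MDA8 ozone fields, survey-weighted stratified fixed-effects
    regression with cluster-robust inference, a varying-coefficient model for
    the nonlinear exposure-response function (ERF) integrated from a minimum
    risk exposure level, and country-level attributable-burden assessment
    with Monte Carlo uncertainty. Ships a synthetic-data generator that
    emulates DHS-like two-stage sampling with a known ground-truth ERF so the
    whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    sandwich,
    splines,
    stats,
    MASS,
    tools,
    utils
Suggests:
    arrow,
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
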