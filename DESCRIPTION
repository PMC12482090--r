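Package: likertsim
Title: Monte Carlo Evaluation of Likert Scales Treated as Continuous Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying what happens when ordinal
    Likert-scale responses are analysed with parametric methods developed for
    continuous data. Responses are modelled as a rectified (clipped) normal
    latent variable with floor and ceiling masses at the scale limits, then
    discretized into 2- to 7-point Likert variables over equal-width
    intervals. The package provides exact moments of both variable types,
    effect-size calibration and attenuation ratios, exchangeably correlated
    multivariate generators, and simulation drivers that quantify type-1
    error, statistical power, required sample sizes, and the preservation of
    correlation structure (GFI, SRMR) under discretization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
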