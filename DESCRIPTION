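Package: nutriangle
Title: Thales-Angle Analysis of Rules of Dietary Compromise in Nutrient Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how animal nutrient-intake arrays deviate from the
    closest-distance-optimisation (CDO) rule of compromise in two-dimensional
    nutrient space. For every observed intake point the package computes the
    inscribed (Thales) angle formed with the origin and the intake target;
    under CDO the intake on every nutritional rail falls on the circle whose
    diameter joins the origin and the target, so the angle is 90 degrees.
    Per-rail deviations from 90 degrees are estimated with pooled-variance
    confidence intervals and ANOVA-style hypothesis tests, noise-stability
    simulations characterise the estimator under Gaussian, Poisson and gamma
    error, and archetypal array generators (CDO, square, equal-distance,
    inverted-square, linear, concave) provide synthetic fixtures. Includes
    nutrient-space and angle-summary plots and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
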