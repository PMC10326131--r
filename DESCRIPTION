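Package: skinaniso
Title: Skin Anisotropy and Stiffness from Angular Elastic-Wave Arrival Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing in vivo skin anisotropy from angular
    elastic-wave arrival-time measurements (Reviscometer-style RRT data).
    Provides direct least-squares ellipse fitting of angular profiles with
    eccentricity, area, anisotropic-ratio and Langer-line direction metrics;
    Rayleigh surface-wave calibration of arrival times to stiffness; a
    Monte-Carlo robustness study comparing eccentricity with the classic
    anisotropic ratio; synthetic cohort generators; and Bayesian inference
    via a conjugate Gibbs sampler for a trivariate-outcome regression of
    anisotropy and stiffness on age, gender and skin tension, plus a
    projected-normal circular regression for the ellipse tilt angle, both
    summarised with highest posterior density intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite
Suggests:
    coda,
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
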