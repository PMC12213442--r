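Package: clutchcurve
Title: Within-Clutch Egg Investment Analysis with Hierarchical GAMMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing within-clutch variation in avian egg
    investment. Simulates or ingests clutch-level egg morphometrics
    (length, breadth, laying order, laying date) together with daily
    minimum temperatures, derives egg volume and sphericity, builds a
    scaled model frame, and fits a hierarchical generalized additive
    mixed model of egg volume over the laying sequence with cubic
    regression spline main effects, isotropic thin plate interaction
    surfaces, random intercepts for year and clutch, and a two-pass
    within-clutch AR(1) residual structure. Includes deviance
    partitioning, concurvity and basis-dimension diagnostics, per-clutch
    ACF/PACF residual-dependence analysis with white-noise bands, and
    the classical last-egg deviation statistic D for comparison with the
    full-sequence strategy estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
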