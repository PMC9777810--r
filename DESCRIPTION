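Package: hydrokin
Title: Two-Level Kinetic Modeling of Enzymatic Milk Protein Hydrolysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the enzymatic hydrolysis of milk
    proteins from pH-stat titration data. Converts cumulative titrant
    volume traces into released alpha-amino concentration and degree of
    hydrolysis, fits the logarithmic kinetic model P = (1/b)*ln(a*b*t + 1)
    to hydrolysis curves by nonlinear least squares, correlates the fitted
    kinetic constants with temperature and protease dose over a central
    composite circumscribed design by polynomial response-surface
    regression with backward elimination and ANOVA, and predicts
    hydrolysis curves and degree of hydrolysis with confidence bands at
    new operating conditions. Includes a seeded simulator of pH-stat
    experiments (logarithmic kinetics, optional first-order enzyme
    inactivation, titrant noise and quantization) so the full
    fit-correlate-predict pipeline can be exercised and validated without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
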