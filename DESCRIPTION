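Package: iohexolGFR
Title: Simplified Iohexol Plasma-Clearance Measurement of GFR in Goats and
    Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Measure glomerular filtration rate (GFR) in goats and pigs
    from the plasma clearance of iohexol after a single intravenous
    bolus.  Implements the three-sample simplified method (terminal
    log-linear fit at 180/240/300 min, one-compartment slope-intercept
    clearance, quadratic correction, body-surface-area normalization)
    together with the machinery used to derive and validate such
    corrections: closed-form one- to three-compartment disposition
    models, population simulation of synthetic goat/pig cohorts with
    inter-individual and inter-occasion variability, per-occasion
    nonlinear least-squares reference clearance estimation with
    compartment-number selection, calibration of candidate correction
    relationships, and Bland-Altman, precision and P30/P10 agreement
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
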