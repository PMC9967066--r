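Package: chamberEF
Title: Exposure-Chamber Emission Factors for ENDS Aerosols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing size-resolved particle emissions from
    electronic nicotine delivery systems (ENDS) measured in a well-mixed
    exposure chamber. Simulates puff-driven chamber concentration time series
    with first-order losses and an instrument sampling model (SMPS/OPS style
    size grids, detection ceiling, measurement noise); estimates first-order
    loss coefficients from post-vaping concentration decay; computes
    loss-corrected total particle emissions and per-puff emission factors in
    number and mass under ventilated and unventilated scenarios; fits
    unimodal and bimodal lognormal models to number size distributions to
    extract geometric mean diameter and geometric standard deviation; and
    aggregates replicate experiments with standard errors and two-group
    t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
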