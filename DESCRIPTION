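Package: srstream
Title: Concentration-Discharge Modelling of Dissolved Strontium-90 in
    Catchment Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-term monitoring series of dissolved
    strontium-90 in small contaminated catchment streams. Implements a
    double-exponential model of the decadal concentration decline, a
    parametric concentration-discharge model in which an exponential
    vertical soil activity profile is flux-weighted by an exponential
    lateral-flow profile (with both a closed-form solution and an
    independent quadrature evaluation), Bayesian calibration of the model
    parameters by Markov chain Monte Carlo, period-wise power-law
    concentration-discharge regression with decay correction and discharge
    binning, trapezoidal wash-off flux accounting against the initial soil
    inventory, and a seeded synthetic generator of biweekly monitoring
    series with a snowmelt-driven seasonal hydrograph.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
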