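Package: forestcollapse
Title: Coupled Forest-Population Collapse Dynamics and Stochastic
    Technological Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a quantitative analysis of deforestation-driven
    population collapse versus technological escape. Implements a
    deterministic logistic humans-forest interaction model with
    no-return-point detection, a dichotomous (telegraph) noise model of
    stop-and-go exponential technological growth with exact first-passage
    sampling, closed-form telegrapher and first-passage densities for the
    symmetric case, and a Monte Carlo experiment estimating the
    probability that technology reaches the Dyson energy limit before the
    ecological point of no return, swept over parameter grids.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
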