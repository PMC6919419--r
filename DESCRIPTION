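Package: etvpd
Title: Analytic Sensitivity of Ecosystem Evapotranspiration to Vapor
    Pressure Deficit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-form Penman-Monteith evapotranspiration (ET) with the
    Medlyn unified stomatal conductance model and underlying water use
    efficiency (uWUE) used to eliminate the implicit dependence of canopy
    conductance on gross primary production.  Provides the explicit ET
    expression, its analytic partial derivative with respect to vapor
    pressure deficit (VPD) factored into a dimensionless sign term and a
    positive environmental scaling term, critical-VPD root finding and
    water-conservative/water-intensive regime classification, a
    generalized stomatal model with free VPD exponents together with the
    closed-form inflection locus separating concave-up from concave-down
    ET-VPD curves, and a deterministic parameter-sweep experiment over
    literature ranges of plant and environmental parameters.  Includes a
    synthetic diurnal forcing generator for batch testing and a command
    line interface emitting CSV tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
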