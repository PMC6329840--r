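Package: heatrisk
Title: Heatwave Hazard, Exposure and Illustrative Risk Index Under Warming Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for projecting global heatwave risk under
    stabilized warming levels (1.5 and 2 degrees C) and alternative
    socioeconomic pathways (SSP1, SSP4). Computes the Heat Wave Magnitude
    Index daily (HWMId) and the TX5x validation index from daily maximum
    temperature, fits generalized extreme value distributions to decadal
    block maxima with L-moment estimators under a non-negative shape
    constraint, derives 500-decade return levels with profile-likelihood
    confidence intervals and parametric-bootstrap Anderson-Darling
    goodness-of-fit tests, normalizes population density and a vulnerability
    proxy (one minus the Human Development Index) through fitted
    Johnson-system distributions, and combines hazard, exposure and
    vulnerability into an Illustrative Risk Index with population-exposure
    tables, ensemble summaries and scenario-difference fields. Includes a
    synthetic-data generator emulating prescribed-SST climate ensembles,
    gridded population projections and country-level HDI tables, plus
    first-order conservative regridding between regular latitude-longitude
    grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
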