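Package: bodyevap
Title: City-Scale Accounting of Water Evaporation from Human Perspiration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the water vapour flux that a city's population
    releases through perspiration and respiration. A steady-state human
    heat-balance model feeds the piecewise (PW) sweat-prediction equation to
    give per-person evaporation rates by activity, season and indoor
    climate; rates are integrated over a daily activity schedule and a
    seasonal weather series, upscaled over a population-density raster to
    district and city totals, converted to per-unit-area evaporation
    intensity, and compared against forest evapotranspiration, green-space
    evaporation and municipal water use. Includes seeded generators for
    synthetic cities (population raster, district labels, land-use grid)
    and seasonal weather so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
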