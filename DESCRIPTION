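Package: dairyshed
Title: Sector-Scale Dairy Intensification, Greenhouse-Gas Accounting and
    Forest Carbon Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to assess the climate-smartness of dairy feed
    intensification at sector scale in East African smallholder systems.
    Attributes forest carbon loss to dairy-cattle grazing from co-registered
    1-km carbon-change, fire, fuelwood and cattle layers (with analytic
    variance propagation), computes IPCC Tier-2 livestock greenhouse-gas
    emissions and milk output for baseline and feed-improvement scenarios
    (forage quality, feed conservation, concentrate supplementation, with
    maize yield-gap closure), derives spatial feed-land demand, land-deficit
    polygons and their buffered feedback on forest carbon, quantifies the
    land footprint and worst-case deforestation emissions of concentrate
    production, and reports combined agriculture-plus-forest mitigation and
    emission intensities. Includes a synthetic-landscape and farm-survey
    generator so the full pipeline is testable without remote-sensing
    downloads, and zonal/correlation/rank-test utilities linking farm
    practice indicators to forest carbon change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
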