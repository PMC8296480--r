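Package: trafshed
Title: District Apportionment of Street-Level Traffic Emissions and
    Mortality Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geo-processing and data-analytic pipeline that apportions
    hourly street-level traffic NOx and PM2.5 emissions (g/km) from a
    polyline road network to administrative districts by length-ratio
    allocation, filters them by peak-hour sets and by a buffered
    human-activity region around building footprints, associates district
    emission totals with district mortality rates (deaths per 100,000,
    averaged over years) by least-squares regression, and flags outlying
    districts with a percentage-of-deviation rule (mean +/- 1 SD band).
    Includes a seeded synthetic-city generator (districts, roads,
    buildings, diurnal per-vehicle emission tables, mortality with a
    planted linear emission-mortality relation and planted outlier
    districts) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
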