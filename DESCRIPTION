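Package: tidewetland
Title: Tide-Aware Dense Time-Series Monitoring of Tidal Wetland Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates tide-confounded multispectral satellite time series of
    coastal wetlands with known truth, detects cover change with per-pixel
    harmonic models that carry a water-level covariate (spectral-break
    detection in the CCDC/COLD lineage), classifies temporal segments into a
    six-class wetland legend including transitional covers and mangrove
    dieback, rasterizes annual cover maps with object-based cleaning, and
    quantifies change with Sen's slope and Mann-Kendall trend tests, 10-year
    moving-window trend strength (acceleration), elevation and latitude
    migration profiles, design-based post-stratified accuracy and
    error-adjusted area estimation, and stratified driver attribution with
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
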