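Package: ensotele
Title: ENSO Teleconnection Exposure and Sensitivity Analysis for Gridded
    Monthly Climate and Productivity Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how El Nino-Southern Oscillation (ENSO)
    variability propagates into terrestrial climate and vegetation
    productivity over gridded monthly data. Classifies ENSO phases from an
    Oceanic Nino Index style series (3-month running mean, +/-0.5 degree C
    threshold), converts monthly raster cubes into detrended smoothed
    anomalies, computes per-pixel phase-conditional lagged Pearson
    correlation maps with significance masking, aggregates several climate
    variables into an Entropy Weight Method exposure index, classifies
    sunlit/shaded gross-primary-productivity sensitivity into a four-class
    typology, and detects lagged productivity transitions. Includes a
    synthetic-data generator with known teleconnection structure so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
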