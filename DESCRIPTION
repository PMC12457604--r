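Package: urbanheat
Title: City-Scale Urban Heat Exposure, Morphology and Adaptation Capacity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening large cities against human-climate-niche
    temperature thresholds under climate scenarios. Aggregates gridded mean
    annual temperature, population and GDP (PPP) within morphological city
    boundaries by cell-center zonal statistics, profiles urban form through
    Local Climate Zone (LCZ) class shares, compares the morphology of
    threshold-exceeding and non-exceeding cities with Welch's t-test, scores
    LCZ-targeted heat-adaptation measures with an expert binary weight matrix,
    and overlays per-city economic capacity. Includes a synthetic-world
    generator with planted ground truth so the full pipeline is testable
    without external gridded datasets.
License: MIT
Encoding: UTF-8
Imports: jsonlite, stats, tools, utils
Suggests: testthat (>= 3.0.0), mgcv, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
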