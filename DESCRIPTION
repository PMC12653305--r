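Package: zndvi
Title: Standardized NDVI Anomaly Mapping and Field Validation for Forest Health Monitoring
Version: 0.1.0
Authors@R: person("Forest", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a Sentinel-2-style forest health
    monitoring pipeline: scene-level cloud prefiltering, per-pixel quality
    bitmask and scene-classification masking, growing-season median
    compositing, NDVI and its standardized anomaly (Z NDVI), a five-class
    damage classification, plot-level extraction against monitoring networks,
    agreement statistics (confusion matrices, Cohen's kappa, R-squared, RMSE)
    versus field defoliation, and a temperature-precipitation drought factor
    (TPF) with regression diagnostics. Ships a synthetic-scene generator with
    known ground truth so the full pipeline is testable without satellite data.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
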