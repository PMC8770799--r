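Package: mowsense
Title: Grassland Mowing-Event Detection from Sentinel-1 Coherence and
    Sentinel-2 NDVI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects grassland mowing events from sparse per-field time
    series of Sentinel-1 interferometric coherence (VV/VH) and Sentinel-2
    NDVI. Implements triplet-based NDVI outlier filtering, exponential
    moving-average and moving-average coherence smoothing, interpolation
    onto a fixed 215-day vegetation-season grid, a 14-feature daily
    representation, a 1-D convolutional network that outputs a daily
    mowing probability for every day of the season, event-level
    evaluation with an asymmetric temporal tolerance window, permutation
    feature importance with backward elimination, and a reject-region
    mechanism that abstains on uncertain season-level predictions.
    Includes a synthetic field-season generator emulating half-oval NDVI
    phenology, mowing signatures, cloud-driven missingness and cloud-mask
    outliers, so the whole pipeline is testable without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
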