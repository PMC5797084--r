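Package: bloomphen
Title: Phytoplankton Bloom Phenology from Gridded Ocean-Colour Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects the timing of seasonal phytoplankton blooms (initiation,
    peak, termination, duration) from 8-day chlorophyll-a time series using the
    threshold-criterion / cumulative-sum method, on area-averaged regional
    series and pixel-by-pixel on gridded fields with a coastal bathymetry mask.
    Includes preprocessing (outlier flagging, least-squares gap-filling, 8-day
    compositing, spatial averaging, anomaly and window statistics), mixed-layer
    depth estimation from temperature profiles via a temperature-difference
    criterion, warm-versus-cold-year composite difference maps, normality-gated
    correlation analysis, and a synthetic-data generator that plants ground
    truth for every estimate the pipeline produces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
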