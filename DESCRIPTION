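Package: phenoyield
Title: Pixel-Scale Crop Yield Estimation from NDVI Phenology with Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating crop yields at the satellite-pixel scale from
    sparse NDVI time series. Fits a five-parameter asymmetric logistic curve to
    irregular per-pixel NDVI observations by bounded least squares, reconstructs
    daily NDVI and extracts phenological characteristics (inflection and peak
    times and values), assembles eight standard predictor layouts per crop,
    calibrates per-crop random-forest regression models against field-measured
    pixel yields, maps yields across a crop mask, and validates by aggregating
    pixel yields to county-level production with RMSE, relative error and
    (adjusted) R-squared metrics. Includes a synthetic irrigation-district scene
    generator emulating 30 m, 2-day-revisit optical sampling with cloud dropout,
    so the whole pipeline is testable without external imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    withr,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
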