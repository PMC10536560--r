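Package: eqiscope
Title: Objective Ecosystem Quality Assessment from Vegetation Indicator Rasters
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An automatic, objective pipeline for assessing vegetation-based
    ecosystem quality from co-registered indicator rasters (leaf area index,
    fractional vegetation cover, gross primary productivity). Sub-annual
    indicator series are composited to annual grids by maximum value
    compositing and harmonized onto one analysis grid by nearest-neighbor
    resampling. Indicator relative densities are computed against stratified
    reference values (eco-geographical zone crossed with vegetation ecosystem
    type), z-score standardized, and combined into a continuous ecosystem
    quality index (EQI) using weights derived from principal component
    analysis of the standardized densities. The EQI is classified into five
    levels by exact Fisher-Jenks natural breaks, and two-epoch change is
    quantified with significance thresholds and per-zone/per-type area
    summaries. A synthetic scenario generator produces fully self-contained
    test data with controllable correlation structure and planted change.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
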