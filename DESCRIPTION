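Package: ecoserv
Title: Raster-Based Ecosystem Service Modelling and Land-Use Driver Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying five ecosystem services on
    categorical land-use rasters: carbon sequestration from per-class pool
    densities, annual water yield via the Budyko-Fu curve, potential soil
    erosion via the Universal Soil Loss Equation with monthly rainfall
    erosivity, habitat quality with distance-decayed threat influence, and
    food-material supply via the equivalent-factor valuation method. Includes
    land-use change accounting (class areas, transfer matrices, change
    statistics), region-level service panels, Pearson trade-off and synergy
    analysis, and land-use driver attribution through hierarchical
    partitioning of R-squared and bidirectional stepwise regression. A
    seeded synthetic-landscape generator produces land-use, climate, soil,
    and region rasters with controlled class proportions, spatial
    autocorrelation, precipitation gradients, and urban-expansion dynamics,
    so the full pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
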