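Package: betascape
Title: Gridded Species Richness, Turnover and Spatially Filtered Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for grid-based macroecological analysis of species
    richness and turnover. Rasterizes species range polygons onto a
    lat/lon grid with a coverage rule, builds presence/absence matrices,
    computes Baselga's beta-diversity components and Simpson-based (bSIM)
    neighborhood turnover fields, derives neighborhood-difference
    environmental predictors, and fits spatially filtered regressions:
    Moran's I correlograms, PCNM spatial eigenvector filters selected by
    minimizing residual autocorrelation, semipartial (partial regression)
    tables and AICc all-subsets model selection with standardized
    coefficients and Akaike weights. Includes a synthetic-continent
    generator with niche-structured virtual species for validating the
    whole pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    geosphere,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    vegan,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
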