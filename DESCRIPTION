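Package: reefscape
Title: Spatial Landscape Metrics and Community-Regime Analysis for Benthic Reef Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Site-level analysis of benthic reef communities from annotated
    photomosaic plots: percent cover from stratified random point counts,
    landscape heterogeneity as the proportion of unlike adjacencies on a
    Voronoi tessellation, structural complexity as multi-resolution linear
    rugosity and profile fractal dimension from gridded depth surfaces, and
    the multivariate community-regime pipeline (Bray-Curtis dissimilarity,
    hierarchical clustering, non-metric multidimensional scaling, ANOSIM,
    permutation PERMANOVA with whole-site block permutation, Mantel
    correlogram, and successional trajectory statistics). A synthetic
    reefscape generator supplies ground-truth plots, time series, and
    multi-island regions so every stage can be verified without survey
    imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    ape,
    yaml,
    withr,
    geosphere
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
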