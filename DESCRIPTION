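Package: sesmap
Title: Social-Ecological Hotspot and Coldspot Mapping for Urban Green Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and integrates polygon-level social and ecological value
    layers for urban green spaces: citizen landscape-value counts from
    participatory mapping surveys, visitor-use density from route tracks,
    forest habitat quality from stand inventories via a sigmoidal
    diameter-volume index, and urban biodiversity from confidence-weighted
    expert elicitation over a biotope raster. Layers are min-max normalized,
    compared with Spearman rank correlations, classified into quantile
    hotspots and coldspots, and their spatial concordance quantified with
    the Jaccard overlap coefficient, pairwise overlay-area accounting and an
    eight-cell management-strategy classification. Includes a deterministic
    synthetic-landscape generator (Voronoi tessellation, planted spatial
    gradients, simulated surveys, tracks, stands and expert tables) so the
    full pipeline can be exercised and validated without external data, and
    lightweight planar-geometry and GeoJSON/ASCII-grid I/O utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
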