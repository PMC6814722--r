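Package: forestintegrity
Title: Forest Structural Condition and Structural Integrity Indices with
    Lidar-Based Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies co-registered tree-cover, canopy-height and
    forest-loss-year rasters into the 18-class Forest Structural Condition
    Index (SCI), combines SCI with a human-footprint pressure weighting into
    the Forest Structural Integrity Index (FSII), and validates SCI against
    foliage height diversity (FHD) computed from classified airborne lidar
    point clouds. Includes height-above-ground normalization by k-nearest
    neighbour inverse-distance-squared interpolation, per-cell Shannon
    diversity of 1 m height bins with a point-density validity rule,
    homogeneous-patch core sampling, an OLS plus random-intercept
    mixed-model comparison suite, and a seeded synthetic landscape and
    point-cloud generator so the full pipeline is exercisable end to end
    without external data. Reads and writes single-band GeoTIFF rasters and
    delimited point-cloud files, with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
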