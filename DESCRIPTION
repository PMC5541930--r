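Package: patchtraits
Title: Patch-Level Landscape Metrics as Plant Functional Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats the spatial arrangement of plant species patches as a set of
    functional traits. From cm-resolution species-patch rasters of vegetation
    plots it identifies patches under a four-neighbour rule, computes patch-level
    and plot-level landscape metrics (mean patch size, patch-size coefficient of
    variation, total edge, number of patches, mean shape index, patch richness,
    Shannon diversity), clusters releves by Bray-Curtis dissimilarity and Ward
    linkage, couples plot-by-metric, plot-by-species and species-by-trait tables
    by RLQ and partial RLQ ordination, and tests trait-metric associations with
    the fourth-corner permutation framework (row and column permutation models
    combined by the max-p rule). A synthetic-study generator with a known
    trait-to-patch-geometry coupling supports power and type-I analyses of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
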