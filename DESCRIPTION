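Package: gutnet
Title: Social Networks and Gut Microbiota Transmission in Wild Rodent
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds wild-rodent social networks from spatiotemporal
    logger detections using a lifespan-adjusted Simple Ratio Index,
    characterises gut microbiota similarity (Jaccard, Bray-Curtis) and
    diversity (Chao1 and Chao-Jost asymptotic estimators) from amplicon
    sequence variant count tables, and tests whether social association
    strength predicts microbiota similarity and whether network
    centrality predicts microbiota richness.  Inference is
    permutation-based throughout: node-label permutations for dyadic
    regression and centrality-trait models, double-semi-partialing MRQAP,
    Mantel tests and PERMANOVA.  Includes an edge-thinning density null,
    a leave-one-bacterial-family-out dropout analysis, and a
    synthetic-data generator with known social-transmission ground truth
    for end-to-end validation.
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
    permute,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
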