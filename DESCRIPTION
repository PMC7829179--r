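Package: morphospace
Title: Functional Morphospace Analysis of Assemblages Along Elevational
    Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a morphological trait space for mixed-scale trait
    tables (Gower dissimilarity and principal coordinates), computes five
    functional diversity indices (convex-hull functional richness, a
    two-axis kernel-density hypervolume, functional evenness, and mean and
    standard deviation of nearest-neighbour distances), standardizes them
    against a trait-label randomization null model, tests phylogenetic
    signal with Blomberg's K, decomposes richness differences between
    adjacent elevational assemblages into morphospace packing and
    expansion, estimates incidence-based (Chao2) richness, and provides
    small-sample information-theoretic model-comparison utilities (AICc,
    Akaike weights, summed-weight variable importance, marginal and
    conditional R2).  A seeded synthetic-data generator produces trait
    tables, pure-birth phylogenies with Brownian traits, and multi-transect
    elevational communities with hump-shaped richness and tunable
    environmental filtering, so every stage of the pipeline can be
    calibrated and power-tested.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    ape,
    vegan,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    picante,
    lme4,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
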