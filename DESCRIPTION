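Package: microsuccession
Title: Ecological Processes Governing Host-Associated Microbiota Succession
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the ecological processes (selection, dispersal, drift)
    that govern microbial community succession in developing hosts, with the
    zebrafish gut/water metacommunity design as the motivating system. Provides
    OTU-table, phylogeny and metadata input/output with rarefaction; alpha and
    beta diversity; Rao quadratic-entropy additive partitioning of metacommunity
    diversity; abundance-weighted beta mean nearest taxon distance (betaMNTD),
    its phylogeny-shuffle z-score (betaNTI), Bray-Curtis-based Raup-Crick
    (RC-bray) null models and the five-way assembly-process classification;
    a richness- and pool-constrained null model of within-group similarity
    ("selection strength"); PERMANOVA, Mantel and partial Mantel tests, ANOVA
    with LSD letters, and hierarchical partitioning of alpha-diversity
    variance; and a synthetic metacommunity generator that emulates a
    hatch/rearing-transition experiment so every stage of the pipeline can be
    validated against known generating parameters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    jsonlite,
    phytools,
    Rcpp,
    stats,
    tibble,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    biomformat,
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
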