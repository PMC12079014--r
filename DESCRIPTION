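Package: ecodecouple
Title: Decoupled Phylogenetic and Functional Community Assembly Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to separate the phylogenetic and the phylogeny-independent
    functional components of species dissimilarity and to test community
    assembly mechanisms along environmental gradients. Implements
    distance decoupling with a shared-fraction diagnostic, abundance-weighted
    MPD and MNTD, tip- and trait-randomization null models with standardized
    effect sizes, turnover/nestedness partitions of taxonomic, phylogenetic
    and functional (convex-hull hypervolume) beta diversity, community
    weighted means, sparse independent principal components of trait
    syndromes, gradient regression helpers, and a synthetic-data generator
    for end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    vegan,
    sandwich,
    lmtest,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
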