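Package: coalselect
Title: Coalescent Model Selection for Stepping-Stone Metapopulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating coalescent model selection against
    F-statistics in high-gene-flow metapopulations. Provides a
    structured-coalescent simulator for haploid sequence data on a
    one-dimensional stepping-stone lattice with post-glacial demographic
    expansion, AMOVA PhiST and Weir-Cockerham theta estimators with Mantel
    tests of isolation by distance, and a Bayesian structured-coalescent
    genealogy sampler with Metropolis-coupled heated chains and
    path-sampling (Bezier-corrected) marginal likelihoods for ranking
    competing metapopulation models (panmixia, island, regional structure,
    stepping-stone).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    vegan,
    coda,
    Matrix
Config/testthat/edition: 3
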