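Package: sibGenoSim
Title: Stochastic Simulation of Selective Genotyping in Sib-Testing Aquaculture Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of a genomic sib-testing
    breeding program for rainbow trout with genotype-by-environment
    interaction between the nucleus (breeding) and commercial production
    environments. Provides a synthetic founder-genome generator with linkage
    disequilibrium, Haldane-model meiosis, partly factorial mating with
    overlapping generations, five phenotype-based selective-genotyping
    strategies under a fixed genotyping budget, uni- and bivariate GBLUP
    evaluation with a VanRaden genomic relationship matrix, AI-REML variance
    component estimation, and the standard breeding-program outcome measures:
    rate of genetic gain, pedigree rate of inbreeding, prediction accuracy,
    and dispersion bias of genomic breeding values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
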