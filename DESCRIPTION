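Package: giltvs
Title: Quantitative Genetics and Genomic Prediction for Vulva Size Traits in Gilts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for the quantitative-genetic analysis of
    vulva size traits in replacement gilts: pedigree-based animal-model
    variance-component estimation (heritability, common-litter environment,
    genetic and phenotypic correlations) by average-information REML;
    whole-genome regression under BayesB, BayesC, BayesCpi and BayesC0
    priors with 1-Mb window variance partitioning for GWAS; sire-family
    cross-validated genomic prediction under within-breed, between-breed,
    multi-breed and QTL-subset strategies; and a breeding-population
    simulator with full ground truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
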