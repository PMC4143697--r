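Package: fbcm
Title: Family-Based Bayesian Collapsing for Rare-Variant Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-level and variant-level rare-variant association testing for
    quantitative traits in nuclear families. Offspring genotypic scores are
    decomposed into orthogonal within-family (transmission deviation) and
    between-family (Mendelian expectation) components, collapsed onto at most
    two low-frequency loci per offspring, and modelled hierarchically with
    variant-specific Bernoulli spike indicators sampled by a conjugate Gibbs
    sampler. Evidence is summarised by a composite-hypothesis hybrid Bayes
    factor per gene and marginal Bayes factors per variant. Includes a family
    simulator for type-I-error and power experiments, VCF/PED/BED/TSV
    ingestion, a genome-wide gene scan, and plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    vcfR,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
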