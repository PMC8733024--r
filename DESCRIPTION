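Package: breedvar
Title: Temporal and Genomic Partitioning of Additive Genetic Variance in
    Breeding Programmes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a multi-stage doubled-haploid plant breeding programme
    with truncation selection and tracks the true additive genetic variance of
    every cohort over time; decomposes genetic variance into genic,
    within-chromosome and between-chromosome linkage-disequilibrium components
    at genome and chromosome level; fits a Bayesian ridge-regression marker
    model (SNP-BLUP) by full-Bayes Gibbs sampling or empirical-Bayes
    conditional sampling through Henderson's mixed model equations, with an
    optional truncated-SVD reduced model; and turns posterior samples of
    marker effects into posterior distributions of temporal and genomic
    variance partitions, scored against the truth with the continuous ranked
    probability score and Lin's concordance correlation coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
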