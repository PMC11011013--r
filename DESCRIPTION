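Package: bayeswgr
Title: Weighted Bayesian Whole-Genome Regression for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A genomic-prediction pipeline for livestock breeding built
    around weighted BayesB and BayesC whole-genome regression. Provides
    SNP quality control (call rate, minor allele frequency,
    Hardy-Weinberg equilibrium), deregression of estimated breeding
    values with reliability-based record weights, Gibbs-sampling mixture
    models over a grid of prior null-marker proportions, 1-Mb-window
    partitioning of posterior genetic variance for association scans,
    pedigree numerator relationship matrices, and relatedness-minimizing
    K-means cross-validation of prediction accuracy. Includes a full
    synthetic-data generator (pedigree, gene-drop genotypes, mixture
    trait architectures, breeding-value records with heterogeneous
    reliabilities) so the whole pipeline can be exercised and tested
    without access to proprietary evaluation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    rtracklayer
Config/testthat/edition: 3
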