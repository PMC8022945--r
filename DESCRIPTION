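Package: zapforest
Title: Zero-Altered Poisson Random Forests for Genomic Prediction of
    Count Traits with Excess Zeros
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-part (hurdle) random forests for non-negative count
    responses with many zeros, aimed at genomic-enabled prediction from
    binary SNP markers across environments. A binary random forest models
    the probability of a zero, and a second forest grown under a
    zero-truncated Poisson log-likelihood splitting criterion models the
    positive counts. Predictions are either the hurdle-model expected
    value (ZAP_RF) or a thresholded classification-style rule (ZAPC_RF).
    The package also provides the conventional least-squares random
    forest, ridge and ridge-penalized Poisson regression baselines, a
    nested cross-validation benchmark with Spearman/MAAPE/MAE metrics,
    permutation variable importance for both model parts, and a synthetic
    genotype/phenotype simulator with marker-driven zero probability and
    truncated-Poisson rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
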