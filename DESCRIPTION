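Package: pathscore
Title: Supervised Transcriptome Classifiers of Aberrant Pathway Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trains, benchmarks, and applies elastic-net penalized logistic
    regression classifiers that detect aberrant gene and pathway activity
    (for example Ras activation) from bulk tumor RNA-seq. Binary aberration
    labels are built by integrating somatic mutation calls with GISTIC-style
    copy-number threshold calls; features are the most variably expressed
    genes by median absolute deviation plus cancer-type and mutation-burden
    covariates. Includes stratified train/test splitting, cross-validated
    hyperparameter search by stochastic gradient descent, shuffled-expression
    null and ablation benchmarking, per-cancer-type and cross-gene
    (phenocopy) evaluation, transfer scoring of external expression profiles
    with within-dataset z-scoring, variant-level score aggregation and the
    associated enrichment and drug-response statistics, and a seeded
    synthetic-cohort generator so the full pipeline is testable without
    restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
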