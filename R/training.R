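#' Training and pipeline configuration
#'
#' Bundles the tunable parameters of the training pipeline. The
#' hyperparameter grids default to the values searched for the Ras task:
#' elastic-net mixing l in \{0.15, 0.155, 0.16, 0.2, 0.25, 0.3, 0.4\} and
#' regularization strength alpha in \{0.1, 0.13, 0.15, 0.18, 0.2, 0.25,
#' 0.3\}.
#'
#' @param test_fraction fraction of samples held out for the final test
#'   partition (stratified by cancer type x status); in (0, 0.5].
#' @param n_folds cross-validation folds within the training partition.
#' @param alpha_grid,l1_ratio_grid hyperparameter grids searched by CV.
#' @param n_mad_genes genes retained by MAD selection (`NULL` = all).
#' @param extra_drop_genes genes dropped from the features in addition to
#'   the target genes.
#' @param standardize standardize gene and burden features on the training
#'   partition.
#' @param include_covariates include cancer-type indicators and log10
#'   mutation burden as (penalized) features.
#' @param include_genes include expression features (disabled by the
#'   covariate-only ablation).
#' @param drop_targets drop target genes from the features (disabled by the
#'   keep-target-genes ablation).
#' @param filter_hypermutators,filter_types apply the burden and
#'   cancer-type sample filters before training.
#' @param min_events,min_proportion cancer-type filter thresholds.
#' @param max_epochs,tol,patience SGD schedule: maximum passes over the
#'   training data, objective-change tolerance, and the number of
#'   consecutive small changes required to stop.
#' @param seed integer seed controlling the split, fold assignment and SGD
#'   sample ordering.
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(test_fraction = 0.10, n_folds = 5,
                              alpha_grid = c(0.1, 0.13, 0.15, 0.18, 0.2, 0.25, 0.3),
                              l1_ratio_grid = c(0.15, 0.155, 0.16, 0.2, 0.25, 0.3, 0.4),
                              n_mad_genes = 8000, extra_drop_genes = NULL,
                              standardize = TRUE, include_covariates = TRUE,
                              include_genes = TRUE, drop_targets = TRUE,
                              filter_hypermutators = TRUE, filter_types = TRUE,
                              min_events = 15, min_proportion = 0.05,
                              max_epochs = 100, tol = 1e-3, patience = 5,
                              seed = 42) {
  stopifnot(test_fraction > 0, test_fraction <= 0.5, n_folds >= 2,
            length(alpha_grid) >= 1, length(l1_ratio_grid) >= 1)
  structure(as.list(environment()), class = "classifier_config")
}

#' Stratified train/test split with cross-validation folds
#'
#' Samples are partitioned into train and test within each (cancer type x
#' status) stratum so both partitions carry the same class and tissue
#' composition (within one sample per stratum). Training samples are then
#' dealt into `n_folds` CV folds, again per stratum. Strata of size 1 go to
#' train. Deterministic given the seed.
#'
#' @param status an [aberration_status()] result (or data.frame with
#'   `sample`, `status`).
#' @param covariates covariate table supplying cancer types.
#' @param config a [classifier_config()].
#' @return data.frame with columns `sample`, `partition` ("train"/"test"),
#'   `fold` (NA for test samples).
#' @export
stratified_split <- function(status, covariates, config = classifier_config()) {
  covariates <- as_covariate_table(covariates)
  st <- status$status[match(covariates$sample, status$sample)]
  if (anyNA(st)) stop("status and covariates are not aligned on samples")
  strat <- paste(as.character(covariates$cancer_type), st, sep = "|")

  set.seed(config$seed)
  out <- data.frame(sample = covariates$sample,
                    partition = "train", fold = NA_integer_,
                    stringsAsFactors = FALSE)
  for (s in unique(strat)) {
    idx <- which(strat == s)
    n_test <- round(config$test_fraction * length(idx))
    if (length(idx) - n_test < 1L) n_test <- length(idx) - 1L
    if (length(idx) == 1L) n_test <- 0L
    shuffled <- if (length(idx) > 1L) sample(idx) else idx
    if (n_test > 0L)
      out$partition[shuffled[seq_len(n_test)]] <- "test"
    tr <- shuffled[setdiff(seq_along(shuffled), seq_len(n_test))]
    out$fold[tr] <- rep_len(seq_len(config$n_folds), length(tr))
  }
  out
}

#' Fit elastic-net penalized logistic regression by stochastic gradient descent
#'
#' Minimizes mean logistic loss plus the elastic-net penalty
#' `alpha * (l1_ratio * ||w||_1 + (1 - l1_ratio) / 2 * ||w||_2^2)` with an
#' unpenalized intercept, using proximal SGD: one sample per step, L2 via
#' multiplicative decay, L1 via soft-thresholding, learning rate
#' `1 / (L0 + alpha * (1 - l1_ratio) * t)` where L0 bounds the per-sample
#' curvature. At the default alpha values many gene weights are exactly
#' zero. Features should be standardized.
#'
#' @param X numeric feature matrix (samples x features), no missing values.
#' @param y 0/1 labels.
#' @param alpha penalty strength.
#' @param l1_ratio elastic-net mixing in \[0, 1\].
#' @param max_epochs,tol,patience stopping rule (see [classifier_config()]).
#' @param seed seed for the per-epoch sample ordering; `NULL` uses the
#'   current RNG state.
#' @return list with `weights` (named by feature), `intercept`,
#'   `objective` (final penalized objective), `epochs`.
#' @export
sgd_elastic_net <- function(X, y, alpha, l1_ratio,
                            max_epochs = 100, tol = 1e-3, patience = 5,
                            seed = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(!anyNA(X), all(y %in% c(0, 1)), alpha >= 0,
            l1_ratio >= 0, l1_ratio <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  perms <- matrix(0L, nrow = max_epochs, ncol = n)
  for (e in seq_len(max_epochs)) perms[e, ] <- sample.int(n) - 1L
  fit <- .sgd_enet_cpp(t(X), y, alpha, l1_ratio,
                       as.integer(max_epochs), tol, as.integer(patience), perms)
  names(fit$weights) <- colnames(X)
  fit
}

#' Penalized logistic objective value
#'
#' Mean logistic loss plus the elastic-net penalty for a given weight
#' vector; used to compare optimizers.
#'
#' @inheritParams sgd_elastic_net
#' @param weights,intercept model parameters.
#' @return scalar objective value.
#' @export
enet_objective <- function(X, y, weights, intercept, alpha, l1_ratio) {
  .enet_objective_cpp(t(as.matrix(X)), as.numeric(y), as.numeric(weights),
                      intercept, alpha, l1_ratio)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

linear_scores <- function(X, weights, intercept) {
  drop(as.matrix(X[, names(weights), drop = FALSE]) %*% weights) + intercept
}

#' Cross-validated hyperparameter grid search
#'
#' For every (alpha, l1_ratio) cell, each CV fold is predicted by a model
#' trained on the remaining folds; the cell's score is the mean AUROC over
#' evaluation folds. Folds containing a single class are skipped with a
#' warning. Ties are broken toward smaller alpha, then smaller l1_ratio.
#'
#' @param X standardized feature matrix over training samples.
#' @param y 0/1 labels over training samples.
#' @param folds integer fold assignment per training sample.
#' @param config a [classifier_config()] supplying the grids and SGD
#'   schedule.
#' @return list with `best_alpha`, `best_l1_ratio`, `grid` (data.frame of
#'   alpha, l1_ratio, mean_cv_auroc, n_folds_used), and `cv_scores`
#'   (out-of-fold prediction scores at the best cell, named by sample).
#' @export
grid_search_cv <- function(X, y, folds, config = classifier_config()) {
  cells <- expand.grid(alpha = config$alpha_grid,
                       l1_ratio = config$l1_ratio_grid,
                       KEEP.OUT.ATTRS = FALSE)
  fold_ids <- sort(unique(folds))
  cell_auroc <- numeric(nrow(cells))
  cell_nfolds <- integer(nrow(cells))
  cv_scores_by_cell <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    a <- cells$alpha[ci]; l <- cells$l1_ratio[ci]
    aucs <- c()
    oof <- rep(NA_real_, length(y))
    for (f in fold_ids) {
      tr <- folds != f; ev <- folds == f
      if (length(unique(y[ev])) < 2L) {
        warning(sprintf("fold %d has a single class; skipped in CV", f),
                call. = FALSE)
        next
      }
      fit <- sgd_elastic_net(X[tr, , drop = FALSE], y[tr], a, l,
                             max_epochs = config$max_epochs, tol = config$tol,
                             patience = config$patience,
                             seed = config$seed + 1000L * f)
      sc <- sigmoid(linear_scores(X[ev, , drop = FALSE], fit$weights,
                                  fit$intercept))
      oof[ev] <- sc
      aucs <- c(aucs, auroc(sc, y[ev]))
    }
    cell_auroc[ci] <- if (length(aucs)) mean(aucs) else NA_real_
    cell_nfolds[ci] <- length(aucs)
    cv_scores_by_cell[[ci]] <- oof
  }
  grid <- cbind(cells, mean_cv_auroc = cell_auroc, n_folds_used = cell_nfolds)
  if (all(is.na(cell_auroc))) stop("no grid cell could be evaluated")
  best <- pick_best_cell(grid)
  list(best_alpha = cells$alpha[best], best_l1_ratio = cells$l1_ratio[best],
       grid = grid,
       cv_scores = setNames(cv_scores_by_cell[[best]], rownames(X)))
}

pick_best_cell <- function(grid) {
  ok <- which(!is.na(grid$mean_cv_auroc))
  ok[order(-grid$mean_cv_auroc[ok], grid$alpha[ok], grid$l1_ratio[ok])][1L]
}
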