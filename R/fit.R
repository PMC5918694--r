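#' Fit a pan-cancer pathway-activity classifier
#'
#' End-to-end training pipeline. In order: hypermutated samples are removed
#' (log10 burden more than 5 SD above the cohort mean); binary aberration
#' status is built from non-silent target-gene mutations and high-gain /
#' deep-loss copy calls; cancer types with too few or too rare target-gene
#' events are excluded; features are the top MAD genes (targets dropped)
#' plus cancer-type indicators and log10 burden; a stratified 90/10
#' train/test split and stratified CV folds are drawn; the elastic-net
#' hyperparameters are chosen by cross-validated AUROC over the grid; the
#' final model is refit on the full training partition at the best cell and
#' evaluated once on the held-out test partition.
#'
#' @param cohort a [cohort()] (expression, mutations, copy number,
#'   covariates over a shared sample set).
#' @param targets a [gene_targets()] declaring oncogenes and tumor
#'   suppressors.
#' @param config a [classifier_config()].
#' @param status optional precomputed [aberration_status()] (used by label
#'   ablations); must cover the cohort samples.
#' @param evidence evidence routes for status construction when `status`
#'   is not supplied ("both", "mutation", "copy").
#' @return an object of class `pathway_classifier`; see
#'   [write_classifier()] for the persistent fields. Extra diagnostic
#'   fields: `grid` (CV grid table), `split`, `metrics` (per-partition
#'   AUROC/AUPR), `scores` (per-sample data.frame with partition, score,
#'   label), `filter_reports`, `retained_types`, `status`.
#' @export
fit_pathway_classifier <- function(cohort, targets,
                                   config = classifier_config(),
                                   status = NULL,
                                   evidence = c("both", "mutation", "copy")) {
  stopifnot(inherits(cohort, "cohort"), inherits(targets, "gene_targets"))
  evidence <- match.arg(evidence)
  reports <- list()

  cov <- cohort$covariates
  if (config$filter_hypermutators) {
    hyper <- filter_hypermutators(cov)
    reports$hypermutators <- hyper
    keep <- hyper$retained
  } else {
    keep <- cov$sample
  }

  if (is.null(status))
    status <- aberration_status(cohort$mutations, cohort$copy_number, targets,
                                samples = rownames(cohort$expression),
                                evidence = evidence)
  status_kept <- status[match(keep, status$sample), , drop = FALSE]
  cov_kept <- cov[match(keep, cov$sample), , drop = FALSE]

  if (config$filter_types) {
    tf <- filter_cancer_types(status_kept, cov_kept,
                              min_events = config$min_events,
                              min_proportion = config$min_proportion)
    reports$cancer_types <- tf
    retained_types <- tf$retained_types
    keep <- tf$retained
    if (length(keep) == 0L)
      stop("no cancer type passes the event filters; nothing to train on")
  } else {
    retained_types <- sort(unique(as.character(cov_kept$cancer_type)))
  }

  sub <- subset_cohort(cohort, keep)
  status_kept <- status[match(keep, status$sample), , drop = FALSE]

  features <- build_feature_matrix(
    sub, if (config$drop_targets) targets else NULL, retained_types,
    n_mad_genes = config$n_mad_genes, extra_drop = config$extra_drop_genes,
    include_genes = config$include_genes,
    include_covariates = config$include_covariates)
  gene_cols <- attr(features, "gene_cols")

  split <- stratified_split(status_kept, sub$covariates, config)
  train_ids <- split$sample[split$partition == "train"]
  test_ids <- split$sample[split$partition == "test"]

  # an indicator constant on the training partition (e.g. a single-type
  # cohort) carries no information and would only duplicate the intercept
  ind_cols <- grep("^type_", colnames(features), value = TRUE)
  dead_ind <- ind_cols[apply(features[train_ids, ind_cols, drop = FALSE], 2L,
                             function(v) length(unique(v)) == 1L)]
  if (length(dead_ind)) {
    features <- features[, setdiff(colnames(features), dead_ind), drop = FALSE]
    if (!length(colnames(features)))
      stop("no informative features remain after dropping constants")
  }

  if (config$standardize) {
    features <- standardize_features(features, fit_on = train_ids)
    gene_cols <- intersect(gene_cols, colnames(features))
  }
  means <- attr(features, "means"); sds <- attr(features, "sds")
  if (is.null(means)) {
    means <- setNames(numeric(0), character(0)); sds <- means
  }

  y <- setNames(status_kept$status, status_kept$sample)
  folds <- split$fold[match(train_ids, split$sample)]
  Xtr <- features[train_ids, , drop = FALSE]

  gs <- grid_search_cv(Xtr, y[train_ids], folds, config)
  final <- sgd_elastic_net(Xtr, y[train_ids], gs$best_alpha, gs$best_l1_ratio,
                           max_epochs = config$max_epochs, tol = config$tol,
                           patience = config$patience, seed = config$seed)

  w <- final$weights
  cov_cols <- setdiff(colnames(features), gene_cols)
  gene_means <- means[intersect(gene_cols, names(means))]
  gene_sds <- sds[intersect(gene_cols, names(sds))]
  # store standardization constants on the original expression scale
  if (!config$standardize) {
    gene_means <- setNames(rep(0, length(gene_cols)), gene_cols)
    gene_sds <- setNames(rep(1, length(gene_cols)), gene_cols)
  }

  model <- new_pathway_classifier(
    gene_weights = w[gene_cols],
    covariate_weights = w[cov_cols],
    intercept = final$intercept,
    alpha = gs$best_alpha, l1_ratio = gs$best_l1_ratio,
    feature_means = gene_means, feature_sds = gene_sds,
    targets = targets, seed = config$seed,
    covariate_means = means[intersect(cov_cols, names(means))],
    covariate_sds = sds[intersect(cov_cols, names(sds))],
    retained_types = retained_types,
    config = config, grid = gs$grid, split = split,
    filter_reports = reports, status = status_kept,
    objective = final$objective, epochs = final$epochs)

  all_scores <- sigmoid(linear_scores(features, w, final$intercept))
  scores <- data.frame(sample = rownames(features), score = all_scores,
                       label = y[rownames(features)],
                       partition = split$partition[match(rownames(features),
                                                         split$sample)],
                       stringsAsFactors = FALSE, row.names = NULL)
  cvs <- gs$cv_scores
  scores$cv_score <- NA_real_
  scores$cv_score[match(names(cvs), scores$sample)] <- cvs

  metrics <- list(
    train = evaluate_scores(scores$score[scores$partition == "train"],
                            scores$label[scores$partition == "train"]),
    cv = with(scores[!is.na(scores$cv_score), ],
              evaluate_scores(cv_score, label)),
    test = if (length(test_ids) &&
               length(unique(scores$label[scores$partition == "test"])) == 2L)
      evaluate_scores(scores$score[scores$partition == "test"],
                      scores$label[scores$partition == "test"]))
  model$scores <- scores
  model$metrics <- metrics
  model
}

subset_cohort <- function(x, samples) {
  cohort(expression = x$expression[samples, , drop = FALSE],
         mutations = x$mutations[x$mutations$sample %in% samples, , drop = FALSE],
         copy_number = x$copy_number[samples, , drop = FALSE],
         covariates = x$covariates[match(samples, x$covariates$sample), ,
                                   drop = FALSE])
}

#' @export
print.pathway_classifier <- function(x, ...) {
  nz <- sum(x$gene_weights != 0)
  cat("pathway_classifier\n")
  cat(sprintf("  targets: oncogenes %s; tumor suppressors %s\n",
              paste(x$targets$oncogenes, collapse = "/"),
              paste(x$targets$tumor_suppressors, collapse = "/")))
  cat(sprintf("  hyperparameters: alpha = %g, l1_ratio = %g\n",
              x$alpha, x$l1_ratio))
  cat(sprintf("  gene features: %d (%d nonzero weights)\n",
              length(x$gene_weights), nz))
  if (!is.null(x$metrics)) {
    for (p in names(x$metrics)) {
      m <- x$metrics[[p]]
      if (!is.null(m))
        cat(sprintf("  %-5s AUROC %.3f  AUPR %.3f  (n = %d, %d positive)\n",
                    p, m$auroc, m$aupr, m$n, m$n_pos))
    }
  }
  invisible(x)
}

#' @export
summary.pathway_classifier <- function(object, n_top = 10, ...) {
  print(object)
  if (!is.null(object$grid)) {
    g <- object$grid[order(-object$grid$mean_cv_auroc), , drop = FALSE]
    cat("\ntop CV grid cells:\n")
    print(head(g, 5L), row.names = FALSE)
  }
  w <- sort(object$gene_weights[object$gene_weights != 0])
  if (length(w)) {
    cat("\nmost negative gene weights:\n")
    print(head(w, n_top))
    cat("\nmost positive gene weights:\n")
    print(tail(w, n_top))
  }
  invisible(object)
}

#' @export
coef.pathway_classifier <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$covariate_weights,
    object$gene_weights)
}

#' Score samples with a fitted classifier
#'
#' Builds the model's feature representation of new cohort data (gene
#' columns standardized with the training constants, covariate block
#' encoded against the training cancer types) and returns the logistic
#' score `1 / (1 + exp(-(w x + b)))`. For external datasets on a different
#' expression scale use [score_external()], which z-scores within the new
#' dataset instead.
#'
#' @param object a `pathway_classifier`.
#' @param cohort a [cohort()] containing the samples to score; expression
#'   must cover all model genes.
#' @param type "response" for scores in (0, 1), "class" for hard 0/1 labels
#'   at threshold 0.5.
#' @param allow_unseen tolerate cancer types outside the training set
#'   (their indicators are zero) — used when scoring excluded types.
#' @param ... unused.
#' @return named numeric (or integer) vector over samples.
#' @export
predict.pathway_classifier <- function(object, cohort,
                                       type = c("response", "class"),
                                       allow_unseen = TRUE, ...) {
  type <- match.arg(type)
  genes <- names(object$gene_weights)
  missing <- setdiff(genes, colnames(cohort$expression))
  if (length(missing))
    stop("expression data lacks model gene(s): ",
         paste(head(missing, 10L), collapse = ", "))
  Xg <- cohort$expression[, genes, drop = FALSE]
  Xg <- sweep(sweep(Xg, 2L, object$feature_means[genes]), 2L,
              object$feature_sds[genes], "/")
  z <- drop(Xg %*% object$gene_weights) + object$intercept
  if (length(object$covariate_weights)) {
    cv <- build_covariates(cohort$covariates, object$retained_types,
                           allow_unseen = allow_unseen)
    cm <- object$covariate_means; cs <- object$covariate_sds
    if (length(cm))
      cv[, names(cm)] <- sweep(sweep(cv[, names(cm), drop = FALSE], 2L, cm),
                               2L, cs, "/")
    cv <- cv[, names(object$covariate_weights), drop = FALSE]
    z <- z + drop(cv %*% object$covariate_weights)
  }
  sc <- sigmoid(z)
  names(sc) <- rownames(cohort$expression)
  if (type == "class") return(as.integer(sc > 0.5))
  sc
}

#' Plot ROC curves of a fitted classifier
#'
#' Base-graphics ROC curves for the train, cross-validation and held-out
#' test partitions, with AUROC in the legend.
#'
#' @param x a `pathway_classifier` with stored per-sample scores.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pathway_classifier <- function(x, ...) {
  if (is.null(x$metrics)) stop("no stored evaluation to plot")
  cols <- c(train = "grey50", cv = "steelblue", test = "firebrick")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey70",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "Classifier ROC", ...)
  leg <- character(); legc <- character()
  for (p in names(x$metrics)) {
    m <- x$metrics[[p]]
    if (is.null(m)) next
    graphics::lines(m$roc$fpr, m$roc$tpr, col = cols[[p]], lwd = 2)
    leg <- c(leg, sprintf("%s AUROC %.3f", p, m$auroc))
    legc <- c(legc, cols[[p]])
  }
  graphics::legend("bottomright", legend = leg, col = legc, lwd = 2, bty = "n")
  invisible(x)
}
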