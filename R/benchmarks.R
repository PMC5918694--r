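#' Permute expression within each gene across samples
#'
#' Breaks the linkage between samples and their expression profiles while
#' preserving every gene's marginal distribution; labels and covariates are
#' left intact by the callers that use this for null models.
#'
#' @param expr expression matrix (samples x genes).
#' @param seed RNG seed (shuffles are reproducible).
#' @return matrix of the same shape and dimnames.
#' @export
shuffle_expression <- function(expr, seed = 1) {
  set.seed(seed)
  shuffled <- apply(expr, 2L, sample)
  rownames(shuffled) <- rownames(expr)
  shuffled
}

#' Shuffled-expression null pipeline
#'
#' Reruns the complete training pipeline on a cohort whose expression
#' matrix has been permuted within genes (covariates and labels intact).
#' With uninformative covariates the held-out test AUROC is expected near
#' 0.5 and the AUPR near the positive prevalence; performance above this
#' baseline on real data therefore reflects expression signal.
#'
#' @param cohort a [cohort()].
#' @param targets a [gene_targets()].
#' @param config a [classifier_config()]; its seed also seeds the shuffle.
#' @return the null-model `pathway_classifier` fit.
#' @export
shuffled_null <- function(cohort, targets, config = classifier_config()) {
  null_cohort <- cohort
  null_cohort$expression <- shuffle_expression(cohort$expression,
                                               seed = config$seed)
  fit_pathway_classifier(null_cohort, targets, config)
}

#' Label and feature ablation battery
#'
#' Reruns the training pipeline with one change at a time, using the same
#' seed so feature-side ablations share a bit-identical sample partition
#' with the full model:
#' \describe{
#'   \item{mutation_only_y / copy_only_y}{labels built from mutation or
#'     copy evidence alone}
#'   \item{keep_target_genes_in_X}{target genes retained in the features}
#'   \item{drop_rasopathy_genes}{the 14-gene RASopathy panel dropped in
#'     addition to the targets}
#'   \item{expression_only_X}{covariate block removed}
#'   \item{covariate_only_X}{expression block removed}
#' }
#' Dropped genes are re-inserted as zero weights in each ablation's
#' `gene_weights` (aligned to the full model's gene set) so coefficient
#' vectors are directly comparable across models.
#'
#' @param cohort,targets,config as for [fit_pathway_classifier()].
#' @param which subset of ablation names to run.
#' @return named list of `pathway_classifier` fits (an ablation whose
#'   labels have no positives is skipped with a recorded message).
#' @export
ablation_battery <- function(cohort, targets, config = classifier_config(),
                             which = c("mutation_only_y", "copy_only_y",
                                       "keep_target_genes_in_X",
                                       "drop_rasopathy_genes",
                                       "expression_only_X",
                                       "covariate_only_X")) {
  which <- match.arg(which, several.ok = TRUE)
  runs <- list()
  for (ab in which) {
    cfg <- config
    ev <- "both"
    if (ab == "mutation_only_y") ev <- "mutation"
    if (ab == "copy_only_y") ev <- "copy"
    if (ab == "keep_target_genes_in_X") cfg$drop_targets <- FALSE
    if (ab == "drop_rasopathy_genes")
      cfg$extra_drop_genes <- union(config$extra_drop_genes, rasopathy_panel)
    if (ab == "expression_only_X") cfg$include_covariates <- FALSE
    if (ab == "covariate_only_X") cfg$include_genes <- FALSE
    runs[[ab]] <- tryCatch(
      fit_pathway_classifier(cohort, targets, cfg, evidence = ev),
      error = function(e) {
        message("ablation '", ab, "' skipped: ", conditionMessage(e))
        structure(list(skipped = TRUE, reason = conditionMessage(e)),
                  class = "skipped_ablation")
      })
  }
  # align gene-weight vectors for cross-model comparison
  gene_union <- sort(unique(unlist(lapply(runs, function(r)
    if (inherits(r, "pathway_classifier")) names(r$gene_weights)))))
  for (ab in names(runs)) {
    if (!inherits(runs[[ab]], "pathway_classifier")) next
    w <- setNames(rep(0, length(gene_union)), gene_union)
    w[names(runs[[ab]]$gene_weights)] <- runs[[ab]]$gene_weights
    runs[[ab]]$aligned_gene_weights <- w
  }
  runs
}

#' Within-cancer-type models versus the pan-cancer model
#'
#' Trains an independently grid-searched classifier on each retained cancer
#' type (no cancer-type indicator covariates within a single type) and
#' tabulates its CV AUROC against the pan-cancer model's CV AUROC restricted
#' to that type. Types failing the event filter, or with single-class
#' labels, are skipped and recorded.
#'
#' @param cohort,targets,config as for [fit_pathway_classifier()].
#' @param pan_fit optional already-fitted pan-cancer model (refit when
#'   `NULL`).
#' @return list with `comparison` (data.frame: type, n, within_cv_auroc,
#'   pan_cv_auroc), `models` (per-type fits), `skipped`.
#' @export
within_type_models <- function(cohort, targets, config = classifier_config(),
                               pan_fit = NULL) {
  if (is.null(pan_fit)) pan_fit <- fit_pathway_classifier(cohort, targets, config)
  types <- pan_fit$retained_types
  models <- list(); skipped <- character(); rows <- list()
  pan_scores <- pan_fit$scores
  pan_types <- as.character(
    cohort$covariates$cancer_type[match(pan_scores$sample,
                                        cohort$covariates$sample)])
  for (tp in types) {
    ids <- cohort$covariates$sample[
      as.character(cohort$covariates$cancer_type) == tp]
    sub <- subset_cohort(cohort, ids)
    cfg <- config
    cfg$filter_types <- FALSE       # a single type is trained as-is
    fit <- tryCatch(fit_pathway_classifier(sub, targets, cfg),
                    error = function(e) NULL)
    if (is.null(fit)) { skipped <- c(skipped, tp); next }
    models[[tp]] <- fit
    pan_sub <- pan_scores[pan_types == tp & !is.na(pan_scores$cv_score), ]
    pan_auc <- if (length(unique(pan_sub$label)) == 2L)
      auroc(pan_sub$cv_score, pan_sub$label) else NA_real_
    rows[[tp]] <- data.frame(type = tp, n = length(ids),
                             within_cv_auroc = fit$metrics$cv$auroc,
                             pan_cv_auroc = pan_auc,
                             stringsAsFactors = FALSE)
  }
  list(comparison = do.call(rbind, rows), models = models,
       skipped = skipped, pan_fit = pan_fit)
}

#' Evaluate an existing classifier against labels for a different gene
#'
#' Scores the model on the given cohort and measures AUROC/AUPR against an
#' alternate status vector (for example NF1-loss labels scored by a Ras
#' classifier), pooled and per cancer type. Optionally restricts the
#' evaluation to samples negative for the model's own target events so
#' phenocopy detection is measured on samples that contributed no training
#' positives.
#'
#' @param model a fitted `pathway_classifier`.
#' @param other_status an [aberration_status()] built from a different
#'   [gene_targets()] over overlapping samples.
#' @param cohort cohort supplying expression/covariates for scoring.
#' @param exclude_own_positives drop samples positive for the model's own
#'   targets before evaluating.
#' @return list with `pooled` (auroc/aupr), `per_type` table, `n`.
#' @export
cross_gene_eval <- function(model, other_status, cohort,
                            exclude_own_positives = FALSE) {
  scores <- predict(model, cohort, allow_unseen = TRUE)
  shared <- intersect(names(scores), other_status$sample)
  if (!length(shared)) stop("no overlap between scored samples and alternate labels")
  if (exclude_own_positives) {
    own <- aberration_status(cohort$mutations, cohort$copy_number,
                             model$targets,
                             samples = rownames(cohort$expression))
    shared <- setdiff(shared, own$sample[own$status == 1L])
  }
  y <- other_status$status[match(shared, other_status$sample)]
  sc <- scores[shared]
  types <- as.character(cohort$covariates$cancer_type[
    match(shared, cohort$covariates$sample)])
  list(pooled = list(auroc = auroc(sc, y), aupr = aupr(sc, y)),
       per_type = per_type_metrics(sc, y, types),
       n = length(shared))
}

#' Evaluate a fitted classifier beyond its training cancer types
#'
#' Scores every sample of a cohort with the fitted model and reports
#' AUROC/AUPR on the full cohort and, separately, on the samples whose
#' cancer types were excluded from training by the event filters (their
#' type indicators are zero at scoring time).
#'
#' @param fit a fitted `pathway_classifier`.
#' @param cohort the full [cohort()] (including excluded types).
#' @param status optional [aberration_status()]; rebuilt from the fit's
#'   targets when `NULL`.
#' @return list with `full_cohort` and `excluded_types` evaluation lists
#'   (each as [evaluate_scores()]), and `n_excluded`.
#' @export
evaluate_partitions <- function(fit, cohort, status = NULL) {
  if (is.null(status))
    status <- aberration_status(cohort$mutations, cohort$copy_number,
                                fit$targets,
                                samples = rownames(cohort$expression))
  sc <- predict(fit, cohort, allow_unseen = TRUE)
  y <- status$status[match(names(sc), status$sample)]
  excl <- !(as.character(cohort$covariates$cancer_type[
    match(names(sc), cohort$covariates$sample)]) %in% fit$retained_types)
  list(full_cohort = evaluate_scores(sc, y),
       excluded_types = if (sum(excl) && length(unique(y[excl])) == 2L)
         evaluate_scores(sc[excl], y[excl]),
       n_excluded = sum(excl))
}

#' Per-gene differential expression with cancer-type adjustment
#'
#' Each gene is zero-one normalized (min-max within gene) and fit by
#' ordinary least squares against the aberration status plus cancer-type
#' indicator variables; the returned statistic is the status coefficient's
#' t-value with two-sided p-values and Benjamini-Hochberg adjustment.
#' Ordinary (unmoderated) per-gene variance estimates are used. Genes
#' constant across samples are flagged rather than fit.
#'
#' @param expr expression matrix (samples x genes).
#' @param status an [aberration_status()] (or data.frame sample/status).
#' @param covariates covariate table supplying cancer types.
#' @return data.frame per gene: `gene`, `estimate`, `t`, `p`, `q`,
#'   `evaluable`.
#' @export
differential_expression <- function(expr, status, covariates) {
  covariates <- as_covariate_table(covariates)
  ids <- rownames(expr)
  y <- status$status[match(ids, status$sample)]
  tp <- as.character(covariates$cancer_type[match(ids, covariates$sample)])
  if (anyNA(y) || anyNA(tp)) stop("status/covariates do not cover all samples")
  if (length(unique(y)) < 2L) stop("both status classes must be present")

  rng <- apply(expr, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  evaluable <- span > 0
  Z <- sweep(sweep(expr, 2L, rng[1L, ]), 2L, pmax(span, 1), "/")
  Z[, evaluable] <- sweep(sweep(expr[, evaluable, drop = FALSE], 2L,
                                rng[1L, evaluable]),
                          2L, span[evaluable], "/")

  design <- cbind(intercept = 1, status = y)
  lv <- sort(unique(tp))
  if (length(lv) > 1L)
    design <- cbind(design, vapply(lv[-1L], function(t2) as.numeric(tp == t2),
                                   numeric(length(tp))))
  qrd <- qr(design)
  df <- nrow(design) - qrd$rank
  coefs <- qr.coef(qrd, Z)
  res <- qr.resid(qrd, Z)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrd))
  se <- sqrt(sigma2 * xtx_inv[2L, 2L])
  tstat <- coefs["status", ] / se
  tstat[!evaluable | se == 0] <- NA_real_
  p <- 2 * pt(-abs(tstat), df)
  data.frame(gene = colnames(expr), estimate = coefs["status", ],
             t = tstat, p = p, q = p.adjust(p, "BH"),
             evaluable = evaluable & is.finite(tstat),
             stringsAsFactors = FALSE, row.names = NULL)
}
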