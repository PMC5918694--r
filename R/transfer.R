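#' Score external expression profiles with a trained classifier
#'
#' Transfer scoring for datasets on a different expression scale (for
#' example cell lines): expression is z-scored per gene *within the
#' external dataset*, subset to the classifier's nonzero-weight genes, and
#' passed through the logistic function of the weighted sum plus intercept.
#' Model genes missing from the data (and genes with zero variance in the
#' data) contribute nothing; covariate terms are omitted because external
#' profiles carry no cancer-type or burden covariates. Scoring is refused
#' when gene coverage falls below `min_coverage`.
#'
#' @param model a `pathway_classifier`.
#' @param expr external expression matrix (profiles x genes), any
#'   per-gene affine scale.
#' @param min_coverage minimum fraction of nonzero-weight model genes that
#'   must be present (default 0.9).
#' @return data.frame of class `transfer_scores`: `profile`, `score`,
#'   `predicted` (hard label at 0.5); attributes `n_model_genes_found`,
#'   `n_model_genes_total`, `coverage`.
#' @export
score_external <- function(model, expr, min_coverage = 0.9) {
  stopifnot(inherits(model, "pathway_classifier"))
  w <- model$gene_weights
  w <- w[w != 0]
  found <- intersect(names(w), colnames(expr))
  coverage <- if (length(w)) length(found) / length(w) else 1
  if (coverage < min_coverage)
    stop(sprintf(
      "gene coverage %.1f%% (%d of %d classifier genes) below the %.0f%% minimum",
      100 * coverage, length(found), length(w), 100 * min_coverage))
  X <- expr[, found, drop = FALSE]
  mu <- colMeans(X)
  sdev <- apply(X, 2L, sd)
  live <- sdev > 0
  Z <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  if (any(live))
    Z[, live] <- sweep(sweep(X[, live, drop = FALSE], 2L, mu[live]), 2L,
                       sdev[live], "/")
  sc <- sigmoid(drop(Z %*% w[found]) + model$intercept)
  structure(data.frame(profile = rownames(expr), score = unname(sc),
                       predicted = as.integer(sc > 0.5),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("transfer_scores", "data.frame"),
            n_model_genes_found = length(found),
            n_model_genes_total = length(w),
            coverage = coverage)
}

#' Confusion-matrix metrics at a score threshold
#'
#' @param scores numeric scores (or a `transfer_scores` data.frame).
#' @param labels 0/1 reference labels in score order.
#' @param threshold hard-label cut (default 0.5).
#' @return list with counts `tp`, `fp`, `tn`, `fn` and percentages
#'   `precision`, `npv`, `accuracy` (0-100 scale; `NA` with a flag when a
#'   predicted class is empty).
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  if (inherits(scores, "transfer_scores")) scores <- scores$score
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  flag <- character()
  if (tp + fp == 0L) flag <- c(flag, "no predicted positives: precision undefined")
  if (tn + fn == 0L) flag <- c(flag, "no predicted negatives: NPV undefined")
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       precision = if (tp + fp > 0L) 100 * tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0L) 100 * tn / (tn + fn) else NA_real_,
       accuracy = 100 * (tp + tn) / length(labels),
       flags = flag)
}

#' Mean classifier score per distinct variant
#'
#' Aggregates profile scores over the distinct (gene, change) keys of the
#' mutation table at nucleotide or protein resolution. Mutation rows whose
#' sample was not scored, or that lack the change field at the requested
#' level, are skipped and counted.
#'
#' @param scores a `transfer_scores` data.frame (or data.frame with
#'   `profile`, `score`).
#' @param mutations mutation table covering the scored profiles.
#' @param level `"nucleotide"` or `"protein"`.
#' @return data.frame: `gene`, `change`, `n_samples`, `mean_score`;
#'   attribute `n_skipped` counts skipped rows.
#' @export
aggregate_variant_scores <- function(scores, mutations,
                                     level = c("nucleotide", "protein")) {
  level <- match.arg(level)
  field <- if (level == "nucleotide") "nucleotide_change" else "protein_change"
  sc <- setNames(scores$score, scores$profile)
  m <- mutations
  m$change <- m[[field]]
  usable <- m$sample %in% names(sc) & !is.na(m$change) & nzchar(m$change)
  skipped <- sum(!usable)
  m <- m[usable, , drop = FALSE]
  if (!nrow(m))
    return(structure(data.frame(gene = character(), change = character(),
                                n_samples = integer(), mean_score = numeric()),
                     n_skipped = skipped))
  key <- paste(m$gene, m$change, sep = "\r")
  agg <- lapply(split(sc[m$sample], key), function(v)
    c(n = length(v), mean = mean(v)))
  keys <- strsplit(names(agg), "\r", fixed = TRUE)
  structure(data.frame(gene = vapply(keys, `[`, "", 1L),
                       change = vapply(keys, `[`, "", 2L),
                       n_samples = vapply(agg, function(a) as.integer(a["n"]), 0L),
                       mean_score = vapply(agg, function(a) a[["mean"]], 0),
                       stringsAsFactors = FALSE, row.names = NULL),
            n_skipped = skipped)
}

#' Chi-square test for a difference in proportions between two groups
#'
#' Pearson chi-square on the 2x2 table `[[k_a, n_a - k_a], [k_b, n_b -
#' k_b]]` with 1 degree of freedom and no continuity correction (used for
#' the COSMIC-annotation enrichment of true positives over false
#' negatives).
#'
#' @param k_a,n_a successes and total in group A.
#' @param k_b,n_b successes and total in group B.
#' @return list with `chi2`, `df`, `p`.
#' @export
enrichment_chi2 <- function(k_a, n_a, k_b, n_b) {
  stopifnot(n_a > 0, n_b > 0, k_a >= 0, k_b >= 0, k_a <= n_a, k_b <= n_b)
  tab <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square undefined: zero margin in the 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Welch two-sample t-test on score groups
#'
#' Independent t-test with unequal variances (Welch-Satterthwaite degrees
#' of freedom), two-sided. Degenerate input with zero variance in both
#' groups and equal means returns t = 0, p = 1.
#'
#' @param scores_a,scores_b numeric score vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
score_group_test <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) >= 2L, length(scores_b) >= 2L)
  if (sd(scores_a) == 0 && sd(scores_b) == 0 &&
      mean(scores_a) == mean(scores_b))
    return(list(t = 0, df = length(scores_a) + length(scores_b) - 2,
                p = 1, mean_a = mean(scores_a), mean_b = mean(scores_b)))
  ht <- t.test(scores_a, scores_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_a = mean(scores_a), mean_b = mean(scores_b))
}

#' Per-drug, per-group regressions of drug activity on classifier scores
#'
#' Fits ordinary least-squares `activity ~ score` separately for each drug
#' within each group (for example mutant and wild-type cell lines) and
#' flags significance at the Bonferroni threshold `0.05 / (n_drugs *
#' n_groups)`. Cells with fewer than `min_n` profiles are flagged and not
#' fit.
#'
#' @param scores named score vector (names = profile ids) or
#'   `transfer_scores`.
#' @param activity data.frame with columns `profile`, `drug`, `activity`.
#' @param groups named 0/1 or character group labels per profile.
#' @param min_n minimum profiles per (drug, group) cell.
#' @return data.frame per (drug, group): `slope`, `se`, `r`, `p`, `n`,
#'   `significant`, `flag`; attribute `bonferroni_threshold`.
#' @export
drug_response_regression <- function(scores, activity, groups, min_n = 3) {
  if (inherits(scores, "transfer_scores"))
    scores <- setNames(scores$score, scores$profile)
  drugs <- sort(unique(activity$drug))
  glab <- sort(unique(as.character(groups)))
  thr <- 0.05 / (length(drugs) * length(glab))
  rows <- list()
  for (d in drugs) for (g in glab) {
    ids <- intersect(names(groups)[as.character(groups) == g],
                     activity$profile[activity$drug == d])
    ids <- intersect(ids, names(scores))
    sub <- activity[activity$drug == d & activity$profile %in% ids, ]
    x <- scores[sub$profile]; yv <- sub$activity
    if (length(x) < min_n || sd(x) == 0) {
      rows[[paste(d, g)]] <- data.frame(drug = d, group = g, slope = NA_real_,
                                        se = NA_real_, r = NA_real_,
                                        p = NA_real_, n = length(x),
                                        significant = FALSE,
                                        flag = "insufficient profiles",
                                        stringsAsFactors = FALSE)
      next
    }
    fit <- stats::lm(yv ~ x)
    sm <- summary(fit)$coefficients
    pval <- sm["x", "Pr(>|t|)"]
    rows[[paste(d, g)]] <- data.frame(
      drug = d, group = g, slope = sm["x", "Estimate"],
      se = sm["x", "Std. Error"], r = stats::cor(x, yv), p = pval,
      n = length(x), significant = is.finite(pval) && pval < thr,
      flag = "", stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            bonferroni_threshold = thr)
}

#' Classifier scores stratified by core status and pathway multi-hits
#'
#' For samples grouped by core target-gene status (0/1) and by the number
#' of additional aberrations in other pathway genes (buckets 0, 1, 2, 3+),
#' summarizes sample count, fraction of scores above 0.5, and mean score.
#' Mutation hits (non-silent mutations in pathway genes outside the core
#' targets) and copy hits (+/-2 calls in those genes) are tabulated
#' separately.
#'
#' @param scores named score vector or `transfer_scores` over samples.
#' @param mutations,cnv cohort evidence tables.
#' @param targets a [gene_targets()] with a non-empty `pathway_genes` list;
#'   core target genes are excluded from the "other hit" counts.
#' @param non_silent variant classes counted as mutation hits.
#' @return list with data.frames `mutation_hits` and `copy_hits`, each
#'   with columns `core_status`, `bucket`, `n`, `fraction_active`,
#'   `mean_score`.
#' @export
multi_hit_stratification <- function(scores, mutations, cnv, targets,
                                     non_silent = non_silent_classes) {
  if (inherits(scores, "transfer_scores"))
    scores <- setNames(scores$score, scores$profile)
  if (is.null(targets$pathway_genes) || !length(targets$pathway_genes))
    stop("targets$pathway_genes must be non-empty for multi-hit analysis")
  core <- c(targets$oncogenes, targets$tumor_suppressors)
  other <- setdiff(targets$pathway_genes, core)
  ids <- names(scores)

  core_status <- aberration_status(mutations, cnv, targets, samples = ids)
  core_y <- core_status$status[match(ids, core_status$sample)]

  rel <- mutations[mutations$gene %in% other &
                     mutations$variant_class %in% non_silent &
                     mutations$sample %in% ids, ]
  mut_hits <- tabulate(match(rel$sample, ids), length(ids))
  other_cnv <- intersect(other, colnames(cnv))
  copy_hits <- if (length(other_cnv))
    rowSums(abs(cnv[ids, other_cnv, drop = FALSE]) == 2L) else
      rep(0L, length(ids))

  bucketize <- function(h) factor(ifelse(h >= 3, "3+", as.character(h)),
                                  levels = c("0", "1", "2", "3+"))
  summarize <- function(hits) {
    b <- bucketize(hits)
    grp <- interaction(core_y, b, drop = TRUE)
    rows <- lapply(levels(grp), function(g) {
      idx <- grp == g
      parts <- strsplit(g, ".", fixed = TRUE)[[1L]]
      data.frame(core_status = as.integer(parts[1L]), bucket = parts[2L],
                 n = sum(idx), fraction_active = mean(scores[idx] > 0.5),
                 mean_score = mean(scores[idx]), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[order(out$core_status, match(out$bucket, c("0", "1", "2", "3+"))), ]
  }
  list(mutation_hits = summarize(mut_hits), copy_hits = summarize(copy_hits))
}
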