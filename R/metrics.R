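#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney identity: the probability that a random
#' positive outranks a random negative, counting ties as one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (or logical).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Uses the average-precision estimator: precision evaluated at the rank of
#' each positive, averaged over positives. No trapezoidal interpolation is
#' applied (interpolation biases PR area upward). Score ties are broken by
#' input order (stable sort).
#'
#' @inheritParams auroc
#' @return AUPR in (0, 1\].
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  if (sum(labels == 1L) == 0L) stop("AUPR undefined: no positive labels")
  ord <- order(-scores)
  y <- labels[ord]
  prec_at_rank <- cumsum(y) / seq_along(y)
  mean(prec_at_rank[y == 1L])
}

#' ROC curve coordinates
#'
#' @inheritParams auroc
#' @return data.frame with columns `fpr`, `tpr` running (0,0) to (1,1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(-scores)
  y <- labels[ord]
  tpr <- c(0, cumsum(y) / sum(y))
  fpr <- c(0, cumsum(1 - y) / sum(1 - y))
  data.frame(fpr = fpr, tpr = tpr)
}

#' Precision-recall curve coordinates
#'
#' @inheritParams auroc
#' @return data.frame with columns `recall`, `precision`.
#' @export
pr_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(-scores)
  y <- labels[ord]
  data.frame(recall = cumsum(y) / sum(y),
             precision = cumsum(y) / seq_along(y))
}

#' AUROC and AUPR within each cancer type
#'
#' Cancer types containing a single label class are flagged as not
#' evaluable rather than raising an error. Note the pooled AUROC is not in
#' general the mean of per-type AUROCs.
#'
#' @inheritParams auroc
#' @param cancer_type per-sample cancer-type labels.
#' @return data.frame with one row per type: `type`, `n`, `n_pos`,
#'   `evaluable`, `auroc`, `aupr`.
#' @export
per_type_metrics <- function(scores, labels, cancer_type) {
  labels <- as.integer(labels)
  sp <- split(seq_along(scores), as.character(cancer_type))
  rows <- lapply(names(sp), function(tp) {
    idx <- sp[[tp]]
    y <- labels[idx]
    ev <- length(unique(y)) == 2L
    data.frame(type = tp, n = length(idx), n_pos = sum(y), evaluable = ev,
               auroc = if (ev) auroc(scores[idx], y) else NA_real_,
               aupr = if (ev) aupr(scores[idx], y) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate scores against labels on one partition
#'
#' @inheritParams auroc
#' @return list with `auroc`, `aupr`, `n`, `n_pos`, and curve point
#'   data.frames `roc` and `pr`.
#' @export
evaluate_scores <- function(scores, labels) {
  labels <- as.integer(labels)
  list(auroc = auroc(scores, labels), aupr = aupr(scores, labels),
       n = length(labels), n_pos = sum(labels),
       roc = roc_points(scores, labels), pr = pr_points(scores, labels))
}
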