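#' Build binary aberration status labels from mutation and copy-number evidence
#'
#' A sample's status is 1 when it carries any non-silent mutation in a target
#' gene, a high copy gain (+2) in a target oncogene, or a deep copy loss (-2)
#' in a target tumor suppressor; otherwise 0. Shallow events (+1/-1) never
#' count. Per-sample evidence flags record which route set the label.
#'
#' @param mutations mutation table (see [as_mutation_table()]).
#' @param cnv copy-number threshold matrix.
#' @param targets a [gene_targets()] object.
#' @param samples sample universe defining the rows of the result; defaults
#'   to the copy-number matrix rows.
#' @param evidence which evidence routes to use; `"both"` (default),
#'   `"mutation"` or `"copy"` (the latter two drive the label-ablation
#'   benchmarks).
#' @param non_silent variant classes counted as non-silent.
#' @return data.frame of class `aberration_status` with columns `sample`,
#'   `status`, `has_mutation_event`, `has_copy_event`.
#' @export
aberration_status <- function(mutations, cnv, targets,
                              samples = rownames(cnv),
                              evidence = c("both", "mutation", "copy"),
                              non_silent = non_silent_classes) {
  evidence <- match.arg(evidence)
  stopifnot(inherits(targets, "gene_targets"))
  target_genes <- c(targets$oncogenes, targets$tumor_suppressors)
  missing_everywhere <- setdiff(target_genes,
                                c(unique(mutations$gene), colnames(cnv)))
  if (length(missing_everywhere))
    warning("target gene(s) absent from both mutation table and CNV matrix: ",
            paste(missing_everywhere, collapse = ", "), call. = FALSE)

  mut_hit <- rep(FALSE, length(samples))
  names(mut_hit) <- samples
  rel <- mutations[mutations$gene %in% target_genes &
                     mutations$variant_class %in% non_silent, , drop = FALSE]
  mut_hit[unique(rel$sample[rel$sample %in% samples])] <- TRUE

  copy_hit <- rep(FALSE, length(samples))
  names(copy_hit) <- samples
  onc <- intersect(targets$oncogenes, colnames(cnv))
  tsg <- intersect(targets$tumor_suppressors, colnames(cnv))
  present <- intersect(samples, rownames(cnv))
  if (length(onc))
    copy_hit[present] <- copy_hit[present] |
      apply(cnv[present, onc, drop = FALSE] == 2L, 1L, any)
  if (length(tsg))
    copy_hit[present] <- copy_hit[present] |
      apply(cnv[present, tsg, drop = FALSE] == -2L, 1L, any)

  use_mut <- evidence %in% c("both", "mutation")
  use_copy <- evidence %in% c("both", "copy")
  status <- as.integer((use_mut & mut_hit) | (use_copy & copy_hit))
  structure(data.frame(sample = samples, status = status,
                       has_mutation_event = unname(mut_hit),
                       has_copy_event = unname(copy_hit),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("aberration_status", "data.frame"))
}

#' Flag hypermutated samples by extreme log10 mutation burden
#'
#' A sample is a hypermutator when its log10(mutation_count + 1) exceeds the
#' cohort mean by more than five standard deviations of the same quantity
#' (the +1 guards zero counts). Hypermutators are likely to carry
#' target-gene mutations by chance and are removed before training.
#'
#' @param covariates covariate table with `mutation_count`.
#' @param n_sd number of standard deviations above the mean (default 5).
#' @return list of class `filter_report` with `removed` (data.frame of
#'   sample, log10_count), `retained` sample ids, and the `threshold` used.
#' @export
filter_hypermutators <- function(covariates, n_sd = 5) {
  covariates <- as_covariate_table(covariates)
  if (nrow(covariates) == 0L) stop("empty cohort: no samples to filter")
  lg <- log10(covariates$mutation_count + 1)
  if (nrow(covariates) < 2L) {
    warning("fewer than 2 samples: burden SD undefined, no samples removed",
            call. = FALSE)
    thr <- Inf
  } else {
    thr <- mean(lg) + n_sd * sd(lg)
  }
  removed <- is.finite(thr) & lg > thr
  structure(list(removed = data.frame(sample = covariates$sample[removed],
                                      log10_count = lg[removed],
                                      stringsAsFactors = FALSE),
                 retained = covariates$sample[!removed],
                 threshold = thr),
            class = "filter_report")
}

#' Retain cancer types with enough target-gene events
#'
#' Keeps cancer types with strictly more than `min_events` positive samples
#' and a positive fraction of at least `min_proportion`, enforcing a
#' reasonably balanced training set; all other types are excluded with the
#' computed quantities recorded.
#'
#' @param status an [aberration_status()] result.
#' @param covariates covariate table aligned to the same samples.
#' @param min_events retain only types with positives > this count.
#' @param min_proportion retain only types with positive fraction >= this.
#' @return list of class `filter_report` with `retained_types`,
#'   `excluded_types` (data.frame type, n, n_events, positive_proportion),
#'   and `retained` sample ids.
#' @export
filter_cancer_types <- function(status, covariates, min_events = 15,
                                min_proportion = 0.05) {
  covariates <- as_covariate_table(covariates)
  st <- status$status[match(covariates$sample, status$sample)]
  if (anyNA(st)) stop("status and covariates are not aligned on samples")
  tab <- do.call(rbind, lapply(split(st, as.character(covariates$cancer_type)),
                               function(v) c(n = length(v), n_events = sum(v))))
  info <- data.frame(type = rownames(tab), n = tab[, "n"],
                     n_events = tab[, "n_events"],
                     positive_proportion = ifelse(tab[, "n"] > 0,
                                                  tab[, "n_events"] / tab[, "n"], NA),
                     stringsAsFactors = FALSE, row.names = NULL)
  keep <- !is.na(info$positive_proportion) &
    info$n_events > min_events & info$positive_proportion >= min_proportion
  retained_types <- info$type[keep]
  structure(list(retained_types = retained_types,
                 excluded_types = info[!keep, , drop = FALSE],
                 type_table = info,
                 retained = covariates$sample[
                   as.character(covariates$cancer_type) %in% retained_types]),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  if (!is.null(x$removed))
    cat(sprintf("hypermutator filter: %d removed (log10 burden > %.3f), %d retained\n",
                nrow(x$removed), x$threshold, length(x$retained)))
  if (!is.null(x$retained_types))
    cat(sprintf("cancer-type filter: %d type(s) retained (%s), %d excluded\n",
                length(x$retained_types),
                paste(x$retained_types, collapse = ", "),
                nrow(x$excluded_types)))
  invisible(x)
}
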