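#' Select the most variably expressed genes by median absolute deviation
#'
#' Ranks genes by MAD = median(|x - median(x)|) across samples (no
#' consistency constant) and returns the `k` largest. Ties are broken by
#' lexicographic gene symbol so builds are deterministic.
#'
#' @param expr expression matrix (samples x genes).
#' @param k number of genes to keep.
#' @return character vector of `k` gene symbols, ordered by decreasing MAD.
#' @export
select_mad_genes <- function(expr, k = 8000) {
  expr <- as_expression_matrix(expr)
  if (k > ncol(expr))
    stop(sprintf("k = %d exceeds the %d available genes", k, ncol(expr)))
  mads <- apply(expr, 2L, function(v) median(abs(v - median(v))))
  ord <- order(-mads, colnames(expr), method = "radix")
  colnames(expr)[ord][seq_len(k)]
}

#' Remove target genes from a feature gene list
#'
#' Target genes are excluded from the expression features so the classifier
#' learns the downstream response rather than dosage effects of the targets
#' themselves. `extra_drop` supports wider panels (e.g. the RASopathy
#' ablation). Genes absent from the list are ignored silently.
#'
#' @param gene_list character vector of candidate feature genes.
#' @param targets a [gene_targets()] object (or NULL to drop nothing).
#' @param extra_drop additional genes to drop.
#' @return the gene list without the dropped genes, order preserved.
#' @export
drop_target_genes <- function(gene_list, targets = NULL, extra_drop = NULL) {
  drop <- extra_drop
  if (!is.null(targets))
    drop <- c(drop, targets$oncogenes, targets$tumor_suppressors)
  setdiff(gene_list, drop)
}

#' Encode cancer-type indicators and log10 mutation burden
#'
#' One 0/1 indicator column per retained cancer type (the full set is kept,
#' with no reference level dropped, because downstream models are
#' penalized) plus a `log10_mutations` column equal to
#' log10(mutation_count + 1).
#'
#' @param covariates covariate table.
#' @param retained_types cancer types to encode; a sample of any other type
#'   is an error unless `allow_unseen = TRUE`, in which case its indicators
#'   are all zero (used when scoring excluded cancer types).
#' @param allow_unseen tolerate cancer types outside `retained_types`.
#' @return numeric matrix with rownames = samples.
#' @export
build_covariates <- function(covariates, retained_types, allow_unseen = FALSE) {
  covariates <- as_covariate_table(covariates)
  type <- as.character(covariates$cancer_type)
  unseen <- setdiff(unique(type), retained_types)
  if (length(unseen) && !allow_unseen)
    stop("cancer type(s) not in the retained set: ",
         paste(unseen, collapse = ", "))
  ind <- matrix(0, nrow(covariates), length(retained_types))
  for (j in seq_along(retained_types))
    ind[, j] <- as.numeric(type == retained_types[j])
  m <- cbind(ind, log10_mutations = log10(covariates$mutation_count + 1))
  colnames(m) <- c(paste0("type_", retained_types), "log10_mutations")
  rownames(m) <- covariates$sample
  m
}

#' Standardize feature columns with constants estimated on a training subset
#'
#' Gene columns and the mutation-burden column are transformed to
#' (x - mean) / SD with mean and SD estimated on `fit_on` rows only and then
#' applied to all rows; 0/1 indicator columns are left untouched. Columns
#' with zero SD on the fitting subset are dropped with a warning.
#'
#' @param features numeric matrix (samples x features).
#' @param fit_on row names (or indices) to estimate constants on; defaults
#'   to all rows.
#' @param skip column names to leave unstandardized (indicator columns).
#' @return the standardized matrix with attributes `means` and `sds`
#'   (named vectors over standardized columns).
#' @export
standardize_features <- function(features, fit_on = rownames(features),
                                 skip = grep("^type_", colnames(features),
                                             value = TRUE)) {
  stopifnot(length(fit_on) > 0L)
  fit <- features[fit_on, , drop = FALSE]
  cols <- setdiff(colnames(features), skip)
  mu <- colMeans(fit[, cols, drop = FALSE])
  sdev <- apply(fit[, cols, drop = FALSE], 2L, sd)
  dead <- cols[sdev == 0 | !is.finite(sdev)]
  if (length(dead)) {
    warning("dropping zero-variance feature(s): ",
            paste(head(dead, 5L), collapse = ", "), call. = FALSE)
    cols <- setdiff(cols, dead)
    features <- features[, setdiff(colnames(features), dead), drop = FALSE]
    mu <- mu[cols]; sdev <- sdev[cols]
  }
  features[, cols] <- sweep(sweep(features[, cols, drop = FALSE], 2L, mu),
                            2L, sdev, "/")
  attr(features, "means") <- mu
  attr(features, "sds") <- sdev
  features
}

#' Assemble the full feature matrix for one cohort
#'
#' MAD gene selection, target-gene dropping and covariate encoding in one
#' deterministic step: gene expression columns (in MAD order) followed by
#' cancer-type indicators and log10 mutation burden.
#'
#' @param cohort a [cohort()].
#' @param targets gene targets whose genes are dropped from the features.
#' @param retained_types cancer types to encode as indicators.
#' @param n_mad_genes number of MAD-selected genes (capped at the gene
#'   count when `NULL`).
#' @param extra_drop additional genes to drop from the features.
#' @param include_genes,include_covariates feature-block switches used by
#'   the expression-only / covariate-only ablations.
#' @param allow_unseen passed to [build_covariates()].
#' @return numeric matrix with rownames = samples; attribute `gene_cols`
#'   names the gene columns.
#' @export
build_feature_matrix <- function(cohort, targets, retained_types,
                                 n_mad_genes = NULL, extra_drop = NULL,
                                 include_genes = TRUE,
                                 include_covariates = TRUE,
                                 allow_unseen = FALSE) {
  blocks <- list()
  gene_cols <- character()
  if (include_genes) {
    k <- if (is.null(n_mad_genes)) ncol(cohort$expression) else n_mad_genes
    genes <- select_mad_genes(cohort$expression, k)
    genes <- drop_target_genes(genes, targets, extra_drop)
    blocks$genes <- cohort$expression[, genes, drop = FALSE]
    gene_cols <- genes
  }
  if (include_covariates)
    blocks$covs <- build_covariates(cohort$covariates, retained_types,
                                    allow_unseen = allow_unseen)
  if (length(blocks) == 0L) stop("at least one feature block is required")
  m <- do.call(cbind, unname(blocks))
  attr(m, "gene_cols") <- gene_cols
  m
}
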