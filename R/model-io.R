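MODEL_FORMAT_VERSION <- 1L

#' Write a fitted classifier to a self-describing text artifact
#'
#' The artifact is a single tab-separated text file with a format-version
#' tag, scalar metadata (hyperparameters, intercept, seed, target genes),
#' a covariate weight table and a gene weight table; weights and
#' standardization constants are printed with 17 significant digits so the
#' round-trip through [read_classifier()] is bit-exact.
#'
#' @param model a `pathway_classifier`.
#' @param path output file.
#' @param prune_zero drop zero-weight genes from the weight table (their
#'   standardization constants are kept for the retained genes only).
#' @return invisibly, `path`.
#' @export
write_classifier <- function(model, path, prune_zero = FALSE) {
  stopifnot(inherits(model, "pathway_classifier"))
  gw <- model$gene_weights
  if (prune_zero) gw <- gw[gw != 0]
  genes <- names(gw)
  covs <- names(model$covariate_weights)
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste0("pathscore_model\t", MODEL_FORMAT_VERSION),
    paste0("alpha\t", num(model$alpha)),
    paste0("l1_ratio\t", num(model$l1_ratio)),
    paste0("intercept\t", num(model$intercept)),
    paste0("seed\t", model$seed),
    paste0("trained\t", model$trained),
    paste0("oncogenes\t", paste(model$targets$oncogenes, collapse = ",")),
    paste0("tumor_suppressors\t",
           paste(model$targets$tumor_suppressors, collapse = ",")),
    paste0("retained_types\t", paste(model$retained_types, collapse = ",")),
    "[covariates]",
    "name\tweight\tmean\tsd",
    if (length(covs)) {
      cm <- setNames(rep(0, length(covs)), covs)
      cs <- setNames(rep(1, length(covs)), covs)
      keep <- intersect(names(model$covariate_means), covs)
      cm[keep] <- model$covariate_means[keep]
      cs[keep] <- model$covariate_sds[keep]
      paste0(covs, "\t", num(model$covariate_weights), "\t", num(cm), "\t",
             num(cs))
    },
    "[genes]",
    "gene\tweight\tmean\tsd",
    if (length(genes)) paste0(genes, "\t", num(gw), "\t",
                              num(model$feature_means[genes]), "\t",
                              num(model$feature_sds[genes])))
  writeLines(lines, path)
  invisible(path)
}

#' Read a classifier artifact written by [write_classifier()]
#'
#' @param path artifact file.
#' @return a `pathway_classifier` carrying the model core (weights,
#'   intercept, hyperparameters, standardization constants, target genes);
#'   training diagnostics (grid table, per-partition scores) are not part
#'   of the artifact.
#' @export
read_classifier <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("truncated classifier artifact: ", path)
  head_parts <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(head_parts) != 2L || head_parts[1L] != "pathscore_model")
    stop("not a pathscore classifier artifact: ", path)
  if (as.integer(head_parts[2L]) != MODEL_FORMAT_VERSION)
    stop(sprintf("classifier artifact format version %s; this build reads version %d",
                 head_parts[2L], MODEL_FORMAT_VERSION))
  sec_cov <- match("[covariates]", lines)
  sec_gene <- match("[genes]", lines)
  if (is.na(sec_cov) || is.na(sec_gene) || sec_gene < sec_cov)
    stop("truncated or corrupt classifier artifact: ", path)

  kv <- strsplit(lines[2:(sec_cov - 1L)], "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", "")
  names(vals) <- keys
  split_genes <- function(s) if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1L]] else character()

  parse_table <- function(block, ncol_expect) {
    block <- block[nzchar(block)]
    if (length(block) < 1L) stop("truncated classifier artifact: ", path)
    rows <- strsplit(block[-1L], "\t", fixed = TRUE)
    if (length(rows) && any(lengths(rows) != ncol_expect))
      stop("truncated classifier artifact: ", path)
    rows
  }
  cov_rows <- parse_table(lines[(sec_cov + 1L):(sec_gene - 1L)], 4L)
  gene_rows <- parse_table(lines[(sec_gene + 1L):length(lines)], 4L)

  cov_names <- vapply(cov_rows, `[`, "", 1L)
  covariate_weights <- setNames(
    vapply(cov_rows, function(r) as.numeric(r[2L]), 0), cov_names)
  covariate_means <- setNames(
    vapply(cov_rows, function(r) as.numeric(r[3L]), 0), cov_names)
  covariate_sds <- setNames(
    vapply(cov_rows, function(r) as.numeric(r[4L]), 0), cov_names)
  std <- covariate_means != 0 | covariate_sds != 1
  genes <- vapply(gene_rows, `[`, "", 1L)
  gene_weights <- setNames(vapply(gene_rows, function(r) as.numeric(r[2L]), 0), genes)
  feature_means <- setNames(vapply(gene_rows, function(r) as.numeric(r[3L]), 0), genes)
  feature_sds <- setNames(vapply(gene_rows, function(r) as.numeric(r[4L]), 0), genes)
  if (any(!is.finite(feature_sds)) || any(feature_sds <= 0))
    stop("classifier artifact has non-positive feature SDs: ", path)

  new_pathway_classifier(
    gene_weights = gene_weights,
    covariate_weights = covariate_weights,
    intercept = as.numeric(vals[["intercept"]]),
    alpha = as.numeric(vals[["alpha"]]),
    l1_ratio = as.numeric(vals[["l1_ratio"]]),
    feature_means = feature_means,
    feature_sds = feature_sds,
    targets = gene_targets(split_genes(vals[["oncogenes"]]),
                           split_genes(vals[["tumor_suppressors"]])),
    seed = as.integer(vals[["seed"]]),
    trained = vals[["trained"]],
    covariate_means = covariate_means[std],
    covariate_sds = covariate_sds[std],
    retained_types = split_genes(vals[["retained_types"]]))
}

new_pathway_classifier <- function(gene_weights, covariate_weights, intercept,
                                   alpha, l1_ratio, feature_means, feature_sds,
                                   targets, seed, trained = format(Sys.time()),
                                   ...) {
  stopifnot(all(names(gene_weights) %in% names(feature_means)),
            all(names(gene_weights) %in% names(feature_sds)))
  structure(c(list(gene_weights = gene_weights,
                   covariate_weights = covariate_weights,
                   intercept = intercept,
                   alpha = alpha, l1_ratio = l1_ratio,
                   feature_means = feature_means,
                   feature_sds = feature_sds,
                   targets = targets, seed = seed, trained = trained),
              list(...)),
            class = "pathway_classifier")
}
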