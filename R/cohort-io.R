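#' Validate a samples-by-genes expression matrix
#'
#' Checks the invariants the pipeline relies on: unique sample and gene
#' identifiers, no missing values, and a numeric matrix shape. Values are
#' continuous expression measurements on any scale that is consistent within
#' the cohort; rows are samples, columns are genes.
#'
#' @param x numeric matrix with sample identifiers as rownames and gene
#'   symbols as colnames.
#' @return the validated matrix (invisibly unchanged).
#' @export
as_expression_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs sample rownames and gene colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers in expression matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyNA(x)) {
    bad <- which(apply(is.na(x), 1L, any))
    stop("missing expression values are not imputed; offending sample(s): ",
         paste(head(rownames(x)[bad], 5L), collapse = ", "))
  }
  x
}

#' Default set of non-silent variant classifications
#'
#' Variant classes counted as evidence of gene aberration when building
#' status labels: protein-altering point mutations, in/out-of-frame indels,
#' splice-site, nonstop and translation-start changes. Configurable via the
#' `non_silent` argument of [aberration_status()].
#'
#' @export
non_silent_classes <- c(
  "Missense_Mutation", "Nonsense_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins",
  "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Nonstop_Mutation", "Translation_Start_Site"
)

#' Validate a long-format somatic mutation table
#'
#' @param x data.frame with columns `sample`, `gene`, `variant_class` and
#'   optional `nucleotide_change`, `protein_change`.
#' @param sample_universe optional character vector; mutation rows whose
#'   sample is outside this universe are an error (mutations must come from
#'   the same cohort).
#' @param vocabulary controlled vocabulary for `variant_class`; rows outside
#'   it are an error. Defaults to the non-silent classes plus the common
#'   silent/non-coding MAF classes.
#' @return the validated data.frame.
#' @export
as_mutation_table <- function(x, sample_universe = NULL,
                              vocabulary = c(non_silent_classes, "Silent",
                                             "3'UTR", "5'UTR", "Intron", "RNA",
                                             "3'Flank", "5'Flank", "IGR")) {
  x <- as.data.frame(x)
  need <- c("sample", "gene", "variant_class")
  if (!all(need %in% names(x)))
    stop("mutation table needs columns: ", paste(need, collapse = ", "))
  if (is.null(x$nucleotide_change)) x$nucleotide_change <- NA_character_
  if (is.null(x$protein_change)) x$protein_change <- NA_character_
  bad <- setdiff(unique(x$variant_class), vocabulary)
  if (length(bad))
    stop("variant_class outside controlled vocabulary: ",
         paste(bad, collapse = ", "))
  if (!is.null(sample_universe)) {
    extra <- setdiff(unique(x$sample), sample_universe)
    if (length(extra))
      stop("mutation table contains samples outside the cohort: ",
           paste(head(extra, 5L), collapse = ", "))
  }
  x[c("sample", "gene", "variant_class", "nucleotide_change", "protein_change")]
}

#' Validate a GISTIC-style copy-number threshold matrix
#'
#' Entries must be integer threshold calls in \{-2, -1, 0, 1, 2\}
#' (deep loss, shallow loss, neutral, gain, high gain).
#'
#' @param x integer matrix, samples in rows, genes in columns.
#' @return validated integer matrix.
#' @export
as_copy_number_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("copy-number matrix needs sample rownames and gene colnames")
  ok <- x %in% c(-2L, -1L, 0L, 1L, 2L)
  if (!all(ok)) {
    idx <- which(!matrix(ok, nrow(x)), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "copy-number call %s at sample '%s', gene '%s' is not in {-2,-1,0,1,2}",
      format(x[idx[1L], idx[2L]]), rownames(x)[idx[1L]], colnames(x)[idx[2L]]))
  }
  storage.mode(x) <- "integer"
  x
}

#' Validate a per-sample covariate table
#'
#' @param x data.frame with columns `sample`, `cancer_type` (non-empty
#'   labels) and `mutation_count` (non-negative total non-silent somatic
#'   mutation counts).
#' @return validated data.frame with one row per sample.
#' @export
as_covariate_table <- function(x) {
  x <- as.data.frame(x)
  need <- c("sample", "cancer_type", "mutation_count")
  if (!all(need %in% names(x)))
    stop("covariate table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(x$sample)) stop("duplicate samples in covariate table")
  if (any(is.na(x$cancer_type) | !nzchar(as.character(x$cancer_type))))
    stop("cancer_type must be non-empty for every sample")
  if (any(is.na(x$mutation_count) | x$mutation_count < 0))
    stop("mutation_count must be a non-negative count")
  x[need]
}

#' Declare the target genes of a classification task
#'
#' Oncogenes count +2 copy gains as aberration evidence; tumor suppressors
#' count -2 deep losses. Any non-silent mutation counts for either class.
#' An optional larger pathway gene list supports multi-hit stratification.
#'
#' @param oncogenes,tumor_suppressors disjoint character vectors of gene
#'   symbols; at least one gene in total.
#' @param pathway_genes optional larger gene list (e.g. 38 Ras-pathway
#'   genes) used by [multi_hit_stratification()].
#' @return an object of class `gene_targets`.
#' @export
gene_targets <- function(oncogenes = character(), tumor_suppressors = character(),
                         pathway_genes = NULL) {
  oncogenes <- as.character(oncogenes)
  tumor_suppressors <- as.character(tumor_suppressors)
  if (length(intersect(oncogenes, tumor_suppressors)))
    stop("oncogene and tumor-suppressor lists must be disjoint")
  if (length(oncogenes) + length(tumor_suppressors) == 0L)
    stop("at least one target gene is required")
  structure(list(oncogenes = oncogenes,
                 tumor_suppressors = tumor_suppressors,
                 pathway_genes = pathway_genes),
            class = "gene_targets")
}

#' The 14-gene expanded RASopathy panel
#'
#' Germline-testing panel of Ras/MAPK pathway genes used for the
#' drop-pathway-genes feature ablation.
#' @export
rasopathy_panel <- c("BRAF", "CBL", "HRAS", "KRAS", "MAP2K1", "MAP2K2", "NF1",
                     "NRAS", "PTPN11", "RAF1", "SHOC2", "SOS1", "SPRED1", "RIT1")

read_tsv_matrix <- function(path) {
  df <- tryCatch(
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse TSV '", path, "': ",
                             conditionMessage(e)))
  if (ncol(df) < 2L) stop("matrix file '", path, "' needs an id column plus data")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Read the four cohort files and align their samples
#'
#' Reads tab-separated files (header row; matrices carry the sample
#' identifier in the first column with genes as columns; the mutation table
#' is long-format and accepts standard MAF column names via `maf_columns`).
#' Samples absent from any required input are dropped with a message; sample
#' order is canonicalized to the sorted intersection so repeated loads agree
#' exactly.
#'
#' @param expression_path,mutation_path,cnv_path,covariate_path TSV paths.
#' @param maf_columns named map from internal column names to the column
#'   names used in the mutation file.
#' @return a list of class `cohort` with elements `expression`, `mutations`,
#'   `copy_number`, `covariates`.
#' @export
load_cohort <- function(expression_path, mutation_path, cnv_path, covariate_path,
                        maf_columns = c(sample = "Tumor_Sample_Barcode",
                                        gene = "Hugo_Symbol",
                                        variant_class = "Variant_Classification",
                                        nucleotide_change = "HGVSc",
                                        protein_change = "HGVSp")) {
  for (p in c(expression_path, mutation_path, cnv_path, covariate_path))
    if (!file.exists(p)) stop("input file does not exist: ", p)

  expr <- as_expression_matrix(read_tsv_matrix(expression_path))
  cnv <- as_copy_number_matrix(read_tsv_matrix(cnv_path))
  cov <- read.delim(covariate_path, check.names = FALSE, stringsAsFactors = FALSE)
  cov <- as_covariate_table(cov)

  mut_raw <- read.delim(mutation_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  for (internal in names(maf_columns)) {
    ext <- maf_columns[[internal]]
    if (!internal %in% names(mut_raw) && ext %in% names(mut_raw))
      names(mut_raw)[names(mut_raw) == ext] <- internal
  }

  shared <- sort(Reduce(intersect, list(rownames(expr), rownames(cnv),
                                        cov$sample)))
  if (length(shared) == 0L)
    stop("no samples shared across expression, copy-number and covariate inputs")
  n_dropped <- length(unique(c(rownames(expr), rownames(cnv), cov$sample))) -
    length(shared)
  if (n_dropped > 0L)
    warning(sprintf("dropped %d sample(s) absent from at least one input",
                    n_dropped), call. = FALSE)

  mut <- as_mutation_table(mut_raw[mut_raw$sample %in% shared, , drop = FALSE],
                           sample_universe = shared)
  cohort(expression = expr[shared, , drop = FALSE],
         mutations = mut,
         copy_number = cnv[shared, , drop = FALSE],
         covariates = cov[match(shared, cov$sample), , drop = FALSE])
}

#' Bundle validated cohort pieces
#'
#' @param expression,mutations,copy_number,covariates see the corresponding
#'   `as_*` validators. All must share the same sample set; expression
#'   row order is the canonical order.
#' @return list of class `cohort`.
#' @export
cohort <- function(expression, mutations, copy_number, covariates) {
  expression <- as_expression_matrix(expression)
  covariates <- as_covariate_table(covariates)
  copy_number <- as_copy_number_matrix(copy_number)
  ids <- rownames(expression)
  if (!setequal(ids, covariates$sample) || !setequal(ids, rownames(copy_number)))
    stop("expression, copy-number and covariate samples do not match")
  mutations <- as_mutation_table(mutations, sample_universe = ids)
  rownames(covariates) <- NULL
  structure(list(expression = expression,
                 mutations = mutations,
                 copy_number = copy_number[ids, , drop = FALSE],
                 covariates = covariates[match(ids, covariates$sample), ,
                                         drop = FALSE]),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d samples, %d expression genes, %d CNV genes, %d mutation rows\n",
              nrow(x$expression), ncol(x$expression), ncol(x$copy_number),
              nrow(x$mutations)))
  cat("cancer types:",
      paste(sort(unique(as.character(x$covariates$cancer_type))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a cohort back to the four TSV files
#'
#' Values are written at full precision (17 significant digits) so a write
#' followed by [load_cohort()] reproduces the numbers exactly.
#'
#' @param x a `cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the four file paths.
#' @export
write_cohort <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "mutations.tsv",
                            "copy_number.tsv", "covariates.tsv"))
  write_matrix_tsv(x$expression, paths[1L])
  write.table(x$mutations, paths[2L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_matrix_tsv(x$copy_number, paths[3L])
  write.table(x$covariates, paths[4L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample = rownames(m),
                   apply(m, 2L, function(v) sprintf("%.17g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (is.integer(m))
    df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
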