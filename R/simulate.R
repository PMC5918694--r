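#' Configuration for the synthetic-cohort generator
#'
#' Describes a multi-cancer-type cohort with a planted expression signature
#' in aberrant samples, mutation-burden heterogeneity including
#' hypermutators, and correlated mutation / copy-number label evidence —
#' the statistical structure the training pipeline assumes.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param cancer_types data.frame with columns `name`, `fraction` (sample
#'   fractions, must sum to 1), `prevalence` (per-type aberration
#'   probability in \[0, 1\]).
#' @param n_signal_genes number of genes carrying the planted signature
#'   (must not exceed `n_genes`); defaults to 10 percent of the genes.
#' @param effect_size mean expression shift, in SD units, of signal genes
#'   in aberrant samples (>= 0).
#' @param copy_fraction fraction of positive labels driven by a +2/-2 copy
#'   call rather than a mutation.
#' @param hypermutator_fraction fraction of samples with a hypermutated
#'   burden (about 50x baseline) and chance target-gene mutations.
#' @param baseline_mutation_rate mean genome-wide non-silent mutation count
#'   per sample; per-sample rates are gamma-distributed (shape 2) so log10
#'   burden has realistic spread.
#' @param oncogenes,tumor_suppressors target genes written into the
#'   mutation and copy-number evidence.
#' @param seed integer seed; identical configs generate bit-identical
#'   cohorts.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1000, n_genes = 2000,
                       cancer_types = data.frame(
                         name = c("TCA", "TCB", "TCC", "TCD"),
                         fraction = c(0.3, 0.3, 0.2, 0.2),
                         prevalence = 0.2),
                       n_signal_genes = ceiling(0.1 * n_genes),
                       effect_size = 1.0,
                       copy_fraction = 0.25, hypermutator_fraction = 0.02,
                       baseline_mutation_rate = 50,
                       oncogenes = c("KRAS", "NRAS", "HRAS"),
                       tumor_suppressors = "NF1",
                       seed = 1) {
  stopifnot(n_samples >= 2, n_genes >= 1)
  if (abs(sum(cancer_types$fraction) - 1) > 1e-9)
    stop("cancer-type sample fractions must sum to 1")
  if (any(cancer_types$prevalence < 0 | cancer_types$prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (n_signal_genes > n_genes) stop("n_signal_genes exceeds n_genes")
  if (copy_fraction < 0 || copy_fraction > 1)
    stop("copy_fraction must lie in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic cohort with known truth
#'
#' Per-sample aberration is drawn from the cancer type's prevalence.
#' Aberrant samples receive either a non-silent mutation in a random target
#' gene or, with probability `copy_fraction`, a +2 copy call (oncogene) /
#' -2 call (tumor suppressor). Baseline expression is standard normal per
#' gene; signal genes are shifted by `effect_size` SD in aberrant samples.
#' Hypermutators get about 50x the baseline burden and chance target-gene
#' mutations at their per-gene background rate (counts scaled to a 20,000
#' gene genome), creating exactly the label noise the hypermutator filter
#' removes; non-hypermutators get no spurious target-gene events. The
#' mutation table carries target-gene rows; background mutations elsewhere
#' are summarized by the burden covariate.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `cohort` (a
#'   [cohort()]), `truth` (data.frame sample, status, evidence,
#'   hypermutator), `signal_genes`, `targets` (a [gene_targets()]).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_genes
  targets <- gene_targets(config$oncogenes, config$tumor_suppressors)
  target_genes <- c(config$oncogenes, config$tumor_suppressors)

  # gene universe: numbered symbols, with the target genes included so
  # target-gene dropping has something to drop
  genes <- sprintf("G%04d", seq_len(p))
  genes[seq_along(target_genes)] <- target_genes
  samples <- sprintf("S%04d", seq_len(n))

  ntypes <- nrow(config$cancer_types)
  counts <- floor(config$cancer_types$fraction * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  type <- rep(as.character(config$cancer_types$name), counts)

  aberrant <- rbinom(n, 1L, config$cancer_types$prevalence[match(
    type, config$cancer_types$name)])
  hyper <- runif(n) < config$hypermutator_fraction

  # burden: gamma-mixed Poisson (negative binomial), hypermutators ~50x
  rate <- rgamma(n, shape = 2, scale = config$baseline_mutation_rate / 2)
  rate[hyper] <- rate[hyper] * 50
  background_count <- rpois(n, rate)

  # planted signature: random signal genes outside the target genes
  candidates <- setdiff(genes, target_genes)
  signal_genes <- sample(candidates, min(config$n_signal_genes,
                                         length(candidates)))
  expr <- matrix(rnorm(n * p), n, p, dimnames = list(samples, genes))
  if (any(aberrant == 1L) && config$effect_size > 0)
    expr[aberrant == 1L, signal_genes] <-
      expr[aberrant == 1L, signal_genes] + config$effect_size

  cnv <- matrix(0L, n, length(target_genes),
                dimnames = list(samples, target_genes))
  mut_rows <- list()
  evidence <- rep(NA_character_, n)
  variant_pool <- data.frame(
    nucleotide = c("c.35G>A", "c.35G>T", "c.34G>T", "c.38G>A", "c.183A>C"),
    protein = c("p.G12D", "p.G12V", "p.G12C", "p.G13D", "p.Q61H"),
    stringsAsFactors = FALSE)

  for (i in which(aberrant == 1L)) {
    g <- sample(target_genes, 1L)
    if (runif(1) < config$copy_fraction) {
      cnv[i, g] <- if (g %in% config$oncogenes) 2L else -2L
      evidence[i] <- "copy"
    } else {
      v <- variant_pool[sample.int(nrow(variant_pool), 1L), ]
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        sample = samples[i], gene = g, variant_class = "Missense_Mutation",
        nucleotide_change = v$nucleotide, protein_change = v$protein,
        stringsAsFactors = FALSE)
      evidence[i] <- "mutation"
    }
  }

  # chance target-gene mutations in hypermutators only (label noise)
  for (i in which(hyper)) {
    p_gene <- min(1, background_count[i] / 20000)
    hit <- target_genes[runif(length(target_genes)) < p_gene]
    for (g in hit)
      mut_rows[[length(mut_rows) + 1L]] <- data.frame(
        sample = samples[i], gene = g, variant_class = "Missense_Mutation",
        nucleotide_change = "c.100A>G", protein_change = "p.T34A",
        stringsAsFactors = FALSE)
  }

  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(sample = character(), gene = character(),
               variant_class = character(), nucleotide_change = character(),
               protein_change = character(), stringsAsFactors = FALSE)
  n_target_rows <- tabulate(match(mutations$sample, samples), n)
  covariates <- data.frame(sample = samples, cancer_type = type,
                           mutation_count = background_count + n_target_rows,
                           stringsAsFactors = FALSE)

  structure(list(
    cohort = cohort(expression = expr, mutations = mutations,
                    copy_number = cnv, covariates = covariates),
    truth = data.frame(sample = samples, status = aberrant,
                       evidence = evidence, hypermutator = hyper,
                       stringsAsFactors = FALSE),
    signal_genes = signal_genes,
    targets = targets), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d samples, %d genes, %d aberrant (%.1f%%), %d hypermutator(s)\n",
              nrow(x$cohort$expression), ncol(x$cohort$expression),
              sum(x$truth$status), 100 * mean(x$truth$status),
              sum(x$truth$hypermutator)))
  invisible(x)
}

#' Generate external expression profiles on a different scale
#'
#' Emulates an independent cell-line dataset: profiles over the given genes
#' on an arbitrary per-gene scale (gene means around `base_mean`, gene SDs
#' drawn from \[0.5, 2\] times `base_sd`), with mutant profiles shifted
#' upward by `effect_size` (in that gene's SD) on the signal genes. Because
#' the scale differs from the training scale, scoring these profiles
#' exercises the within-dataset z-scoring of [score_external()].
#'
#' @param genes gene symbols the profiles cover.
#' @param signal_genes genes carrying the mutant signature (subset of
#'   `genes`).
#' @param n_profiles number of profiles (>= 2).
#' @param mutant_fraction fraction of profiles labeled mutant, in \[0, 1\].
#' @param effect_size signature shift in per-gene SD units.
#' @param seed RNG seed.
#' @param base_mean,base_sd location and scale of the per-gene baselines.
#' @return list with `expression` (profiles x genes matrix) and `labels`
#'   (0/1 mutant indicator named by profile).
#' @export
simulate_external_profiles <- function(genes, signal_genes, n_profiles,
                                       mutant_fraction, effect_size = 1,
                                       seed = 1, base_mean = 8, base_sd = 1) {
  stopifnot(n_profiles >= 2)
  if (mutant_fraction < 0 || mutant_fraction > 1)
    stop("mutant_fraction must lie in [0, 1]")
  set.seed(seed)
  p <- length(genes)
  ids <- sprintf("CL%03d", seq_len(n_profiles))
  n_mut <- round(mutant_fraction * n_profiles)
  labels <- setNames(c(rep(1L, n_mut), rep(0L, n_profiles - n_mut)), ids)
  mu <- rnorm(p, base_mean, 2)
  sdev <- runif(p, 0.5, 2) * base_sd
  z <- matrix(rnorm(n_profiles * p), n_profiles, p,
              dimnames = list(ids, genes))
  sig <- intersect(signal_genes, genes)
  if (n_mut > 0 && length(sig))
    z[labels == 1L, sig] <- z[labels == 1L, sig] + effect_size
  expr <- sweep(sweep(z, 2L, sdev, "*"), 2L, mu, "+")
  list(expression = expr, labels = labels)
}
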