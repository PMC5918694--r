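# Small hand-built cohort fixtures plus a cache for expensive shared fits.

tiny_cohort <- function(n = 10, p = 6, seed = 99, types = c("AA", "BB")) {
  set.seed(seed)
  samples <- sprintf("P%02d", seq_len(n))
  genes <- c("KRAS", sprintf("g%02d", seq_len(p - 1)))
  expr <- matrix(rnorm(n * p), n, p, dimnames = list(samples, genes))
  cnv <- matrix(0L, n, 2L, dimnames = list(samples, c("KRAS", "NF1")))
  mut <- data.frame(sample = samples[1], gene = "KRAS",
                    variant_class = "Missense_Mutation",
                    nucleotide_change = "c.35G>A", protein_change = "p.G12D",
                    stringsAsFactors = FALSE)
  cov <- data.frame(sample = samples,
                    cancer_type = rep(types, length.out = n),
                    mutation_count = rpois(n, 30), stringsAsFactors = FALSE)
  cohort(expression = expr, mutations = mut, copy_number = cnv,
         covariates = cov)
}

write_cohort_fixture <- function(dir, ...) {
  co <- tiny_cohort(...)
  write_cohort(co, dir)
  co
}

# session-level cache so expensive simulated fits are shared across tests
.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) assign(key, expr, envir = .fit_cache)
  get(key, envir = .fit_cache)
}

# full-scale planted-signal cohort and pipeline fit (signal recovery checks)
recovery_fit <- function() {
  cached("recovery", {
    sim <- simulate_cohort(sim_config(seed = 101))
    cfg <- classifier_config(n_mad_genes = 2000,
                             alpha_grid = c(0.1, 0.2),
                             l1_ratio_grid = c(0.15, 0.4), seed = 101)
    list(sim = sim, fit = fit_pathway_classifier(sim$cohort, sim$targets, cfg))
  })
}

# mid-sized cohort for cheaper pipeline-level tests
small_sim <- function(seed = 7, n = 500, p = 300, ...) {
  simulate_cohort(sim_config(n_samples = n, n_genes = p, seed = seed, ...))
}

small_config <- function(seed = 7, p = 300, ...) {
  classifier_config(n_mad_genes = p, alpha_grid = 0.1, l1_ratio_grid = 0.15,
                    seed = seed, ...)
}
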