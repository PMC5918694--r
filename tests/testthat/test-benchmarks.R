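test_that("within-gene shuffling is seeded and preserves gene marginals", {
  sim <- small_sim(seed = 41, n = 50, p = 20)
  a <- shuffle_expression(sim$cohort$expression, seed = 5)
  b <- shuffle_expression(sim$cohort$expression, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, sim$cohort$expression))
  for (g in colnames(a))
    expect_identical(sort(unname(a[, g])),
                     sort(unname(sim$cohort$expression[, g])))
})

test_that("feature-side ablations share a bit-identical sample partition", {
  sim <- small_sim(seed = 43, n = 300, p = 80)
  cfg <- small_config(seed = 43, p = 80)
  runs <- ablation_battery(sim$cohort, sim$targets, cfg,
                           which = c("expression_only_X",
                                     "keep_target_genes_in_X",
                                     "drop_rasopathy_genes"))
  full <- fit_pathway_classifier(sim$cohort, sim$targets, cfg)
  for (ab in names(runs))
    expect_identical(runs[[ab]]$split, full$split, label = ab)
  # dropped genes come back as comparable zero weights
  expect_true(all(sim$targets$oncogenes %in%
                    names(runs$keep_target_genes_in_X$aligned_gene_weights)))
  kept <- runs$drop_rasopathy_genes$aligned_gene_weights
  expect_true(all(kept[intersect(rasopathy_panel, names(kept))] == 0))
})

test_that("covariate-only models carry no signal when it sits in expression", {
  sim <- small_sim(seed = 47, n = 500, p = 120)
  cfg <- small_config(seed = 47, p = 120)
  runs <- ablation_battery(sim$cohort, sim$targets, cfg,
                           which = "covariate_only_X")
  m <- runs$covariate_only_X$metrics$test
  se <- sqrt(1 / (4 * m$n_pos) + 1 / (4 * (m$n - m$n_pos)))
  expect_lt(abs(m$auroc - 0.5), 3 * se + 0.05)
})

test_that("mutation-only labels equal combined labels when no positives are copy-driven", {
  sim <- simulate_cohort(sim_config(n_samples = 300, n_genes = 60,
                                    copy_fraction = 0, seed = 51))
  both <- aberration_status(sim$cohort$mutations, sim$cohort$copy_number,
                            sim$targets)
  mut <- aberration_status(sim$cohort$mutations, sim$cohort$copy_number,
                           sim$targets, evidence = "mutation")
  expect_identical(both$status, mut$status)
})

test_that("cross-gene evaluation reproduces the standard one on identical labels", {
  rec <- recovery_fit()
  ev <- cross_gene_eval(rec$fit, rec$fit$status, rec$sim$cohort)
  sc <- predict(rec$fit, rec$sim$cohort, allow_unseen = TRUE)
  shared <- intersect(names(sc), rec$fit$status$sample)
  direct <- auroc(sc[shared],
                  rec$fit$status$status[match(shared, rec$fit$status$sample)])
  expect_equal(ev$pooled$auroc, direct)
})

test_that("labels independent of the signature score at chance", {
  rec <- recovery_fit()
  set.seed(61)
  rand_status <- data.frame(sample = rec$sim$truth$sample,
                            status = rbinom(nrow(rec$sim$truth), 1, 0.2))
  ev <- cross_gene_eval(rec$fit, rand_status, rec$sim$cohort)
  n_pos <- sum(rand_status$status)
  se <- sqrt(1 / (4 * n_pos) + 1 / (4 * (ev$n - n_pos)))
  expect_lt(abs(ev$pooled$auroc - 0.5), 3 * se + 0.02)
})

test_that("a second gene planting the same signature is detected (phenocopy)", {
  rec <- recovery_fit()
  sim <- rec$sim
  # train on KRAS events only; NRAS/HRAS/NF1-driven samples are phenocopies
  kras_only <- gene_targets("KRAS")
  # single-gene labels are ~4x rarer, so per-type event thresholds scale down
  cfg <- classifier_config(n_mad_genes = 2000, alpha_grid = 0.1,
                           l1_ratio_grid = 0.15, seed = 101,
                           min_events = 5, min_proportion = 0.02)
  fit_a <- cached("kras_only_fit",
                  fit_pathway_classifier(sim$cohort, kras_only, cfg))
  other <- aberration_status(sim$cohort$mutations, sim$cohort$copy_number,
                             gene_targets("NRAS"))
  ev <- cross_gene_eval(fit_a, other, sim$cohort,
                        exclude_own_positives = TRUE)
  expect_gt(ev$pooled$auroc, 0.8)
})

test_that("within-type models are comparable to the pan-cancer model per type", {
  sim <- cached("wt_sim", simulate_cohort(sim_config(
    n_samples = 600, n_genes = 150,
    cancer_types = data.frame(name = c("TCA", "TCB"), fraction = c(0.5, 0.5),
                              prevalence = 0.25),
    seed = 71)))
  cfg <- classifier_config(n_mad_genes = 150, alpha_grid = 0.1,
                           l1_ratio_grid = 0.15, seed = 71)
  res <- cached("wt_res", within_type_models(sim$cohort, sim$targets, cfg))
  expect_setequal(res$comparison$type, c("TCA", "TCB"))
  # shared planted signature: per-type CV AUROCs agree within noise
  expect_true(all(abs(res$comparison$within_cv_auroc -
                        res$comparison$pan_cv_auroc) < 0.1))
})

test_that("types with single-class labels are skipped by within-type training", {
  sim <- small_sim(seed = 73, n = 200, p = 50)
  co <- sim$cohort
  # make type TCD all-negative by erasing its evidence
  td <- co$covariates$sample[co$covariates$cancer_type == "TCD"]
  co$mutations <- co$mutations[!co$mutations$sample %in% td, ]
  co$copy_number[td, ] <- 0L
  cfg <- classifier_config(n_mad_genes = 50, alpha_grid = 0.1,
                           l1_ratio_grid = 0.15, seed = 73,
                           filter_types = FALSE, min_events = 2)
  res <- within_type_models(co, sim$targets, cfg)
  expect_true("TCD" %in% res$skipped)
})

test_that("excluded cancer types can still be scored and evaluated", {
  sim <- cached("excl_sim", simulate_cohort(sim_config(
    n_samples = 500, n_genes = 120,
    cancer_types = data.frame(name = c("TCA", "TCB", "TCR"),
                              fraction = c(0.45, 0.45, 0.1),
                              prevalence = c(0.25, 0.25, 0.02)),
    seed = 77)))
  # the rare-event type TCR fails the event filter but is still scorable
  cfg <- classifier_config(n_mad_genes = 120, alpha_grid = 0.1,
                           l1_ratio_grid = 0.15, seed = 77, min_events = 10)
  fit <- fit_pathway_classifier(sim$cohort, sim$targets, cfg)
  expect_false("TCR" %in% fit$retained_types)
  ev <- evaluate_partitions(fit, sim$cohort)
  expect_equal(ev$n_excluded,
               sum(sim$cohort$covariates$cancer_type == "TCR"))
  expect_true(ev$full_cohort$auroc > 0.8)
})

test_that("differential expression recovers planted signal and respects confounding", {
  set.seed(81)
  n <- 500
  type <- rep(c("A", "B"), each = n / 2)
  y <- rbinom(n, 1, 0.3)
  expr <- cbind(signal = rnorm(n) + 1.0 * y,
                confounded = rnorm(n) + 2 * (type == "B"),
                flat = rep(1, n),
                noise = rnorm(n))
  rownames(expr) <- sprintf("s%d", 1:n)
  st <- data.frame(sample = rownames(expr), status = y)
  cov <- data.frame(sample = rownames(expr), cancer_type = type,
                    mutation_count = 10)
  de <- differential_expression(expr, st, cov)
  expect_gt(abs(de$t[de$gene == "signal"]), 5)
  expect_lt(de$q[de$gene == "signal"], 0.01)
  # between-type variation absorbed by the covariate: status effect near zero
  expect_lt(abs(de$t[de$gene == "confounded"]), 3)
  expect_false(de$evaluable[de$gene == "flat"])
  expect_true(is.na(de$t[de$gene == "flat"]))

  # per-gene affine rescaling before zero-one normalization changes nothing
  expr2 <- expr
  expr2[, "signal"] <- 100 * expr[, "signal"] - 7
  de2 <- differential_expression(expr2, st, cov)
  expect_equal(de2$t[de2$gene == "signal"], de$t[de$gene == "signal"],
               tolerance = 1e-10)
})

test_that("planted differential-expression t grows with sample size", {
  tvals <- vapply(c(120, 500), function(n) {
    set.seed(n)
    y <- rbinom(n, 1, 0.5)
    expr <- cbind(sig = rnorm(n) + 1.0 * y, noise = rnorm(n))
    rownames(expr) <- sprintf("s%d", 1:n)
    de <- differential_expression(
      expr, data.frame(sample = rownames(expr), status = y),
      data.frame(sample = rownames(expr), cancer_type = "A",
                 mutation_count = 5))
    abs(de$t[de$gene == "sig"])
  }, 0)
  expect_gt(tvals[2], tvals[1])
  # closed-form power scale: |t| ~ d * sqrt(n) / 2
  expect_equal(tvals[2], 1.0 * sqrt(500) / 2, tolerance = 0.35)
})
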