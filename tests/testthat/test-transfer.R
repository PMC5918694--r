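toy_model <- function(weights = c(gA = 1.2, gB = -0.8, gC = 0.5),
                      intercept = -0.3) {
  nm <- names(weights)
  pathscore:::new_pathway_classifier(
    gene_weights = weights, covariate_weights = numeric(),
    intercept = intercept, alpha = 0.1, l1_ratio = 0.15,
    feature_means = setNames(rep(0, length(nm)), nm),
    feature_sds = setNames(rep(1, length(nm)), nm),
    targets = gene_targets("KRAS"), seed = 1L)
}

test_that("transfer scoring is invariant to per-gene affine transforms and gene order", {
  set.seed(3)
  model <- toy_model()
  expr <- matrix(rnorm(60), 20, 3,
                 dimnames = list(sprintf("c%02d", 1:20), c("gA", "gB", "gC")))
  base <- score_external(model, expr)
  shifted <- sweep(sweep(expr, 2, c(3, 0.5, 100), "*"), 2, c(-7, 2, 1000), "+")
  expect_equal(score_external(model, shifted)$score, base$score,
               tolerance = 1e-12)
  reordered <- expr[, c("gC", "gA", "gB")]
  expect_equal(score_external(model, reordered)$score, base$score)
})

test_that("degenerate external profiles fall back to the intercept score", {
  model <- toy_model()
  expr <- matrix(5, 4, 3, dimnames = list(sprintf("c%d", 1:4),
                                          c("gA", "gB", "gC")))
  ts <- score_external(model, expr)
  expect_equal(ts$score, rep(1 / (1 + exp(0.3)), 4))
})

test_that("scoring is refused below the minimum gene coverage", {
  w <- setNames(rep(0.5, 10), sprintf("g%02d", 1:10))
  model <- toy_model(weights = w)
  expr <- matrix(rnorm(40), 5, 8,
                 dimnames = list(sprintf("c%d", 1:5), sprintf("g%02d", 1:8)))
  expect_error(score_external(model, expr), "coverage 80.0%")
  ts <- score_external(model, expr, min_coverage = 0.7)
  expect_equal(attr(ts, "n_model_genes_found"), 8)
  expect_equal(attr(ts, "n_model_genes_total"), 10)
})

test_that("mutant external profiles score above wild-types at planted effect", {
  set.seed(9)
  w <- setNames(rep(0.4, 30), sprintf("g%02d", 1:30))
  model <- toy_model(weights = w, intercept = 0)
  ext <- simulate_external_profiles(names(w), names(w)[1:15], n_profiles = 40,
                                    mutant_fraction = 0.5, effect_size = 1,
                                    seed = 10)
  ts <- score_external(model, ext$expression)
  wt <- ts$score[ext$labels == 0]; mu <- ts$score[ext$labels == 1]
  expect_lt(wilcox.test(mu, wt, alternative = "greater")$p.value, 0.05)
})

test_that("confusion metrics reproduce printed cell-line counts", {
  # 344 predicted mutant (153 truly mutant), 393 predicted wild-type
  # (357 truly wild-type): 737 lines total
  labels <- c(rep(1, 153), rep(0, 191), rep(0, 357), rep(1, 36))
  scores <- c(rep(0.9, 344), rep(0.1, 393))
  cm <- confusion_metrics(scores, labels)
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 737)
  expect_equal(round(cm$npv, 1), 90.8)
  expect_equal(round(cm$precision, 1), 44.5)
  expect_equal(round(cm$accuracy, 1), 69.2)
})

test_that("confusion metrics handle perfect and one-sided predictions", {
  cm <- confusion_metrics(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(c(cm$precision, cm$npv, cm$accuracy), c(100, 100, 100))
  cm2 <- confusion_metrics(rep(0.1, 10), rep(c(1, 0), c(3, 7)))
  expect_true(is.na(cm2$precision))
  expect_match(cm2$flags, "precision", all = FALSE)
  expect_equal(cm2$npv, 70)
})

test_that("variant score aggregation keys by level and conserves counts", {
  scores <- data.frame(profile = c("c1", "c2", "c3"),
                       score = c(0.4, 0.6, 0.8))
  muts <- data.frame(sample = c("c1", "c2", "c3"),
                     gene = "KRAS",
                     variant_class = "Missense_Mutation",
                     nucleotide_change = c("c.35G>A", "c.35G>C", "c.34G>T"),
                     protein_change = c("p.G12D", "p.G12D", "p.G12C"))
  nt <- aggregate_variant_scores(scores, muts, level = "nucleotide")
  expect_equal(nrow(nt), 3)
  aa <- aggregate_variant_scores(scores, muts, level = "protein")
  expect_equal(nrow(aa), 2)
  g12d <- aa[aa$change == "p.G12D", ]
  expect_equal(g12d$n_samples, 2L)
  expect_equal(g12d$mean_score, 0.5)
  # sum of per-variant counts equals the usable (sample, variant) pairs
  expect_equal(sum(nt$n_samples), 3L)
  expect_equal(sum(aa$n_samples), 3L)
  # unscored samples and missing change fields are skipped with a count
  muts2 <- rbind(muts, data.frame(sample = c("c9", "c1"), gene = "KRAS",
                                  variant_class = "Missense_Mutation",
                                  nucleotide_change = c("c.1A>G", NA),
                                  protein_change = c("p.X1Y", NA)))
  nt2 <- aggregate_variant_scores(scores, muts2, level = "nucleotide")
  expect_equal(attr(nt2, "n_skipped"), 2L)
})

test_that("proportion chi-square matches printed and hand-computed tables", {
  res <- enrichment_chi2(144, 152, 22, 34)
  expect_equal(round(res$chi2, 1), 26.1)
  expect_equal(res$df, 1)
  expect_equal(signif(res$p, 1), 3e-7)
  expect_equal(enrichment_chi2(10, 20, 10, 20)$chi2, 0)
  # expected counts all 20 -> 4 * (10^2 / 20)
  expect_equal(enrichment_chi2(30, 40, 10, 40)$chi2, 20)
  expect_error(enrichment_chi2(0, 5, 0, 7), "zero margin")
})

test_that("Welch test behaves at the degenerate point and is antisymmetric", {
  res <- score_group_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(c(res$t, res$p), c(0, 1))
  set.seed(17)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  ab <- score_group_test(a, b); ba <- score_group_test(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
})

test_that("Welch test has near-full power at effect 1 with n = 100", {
  set.seed(23)
  rejections <- replicate(100, {
    score_group_test(rnorm(100), rnorm(100, 1))$p < 0.05
  })
  expect_gt(mean(rejections), 0.99)
})

test_that("drug-response regressions flag at the Bonferroni threshold", {
  set.seed(31)
  ids <- sprintf("c%03d", 1:40)
  scores <- setNames(runif(40), ids)
  groups <- setNames(rep(c("mutant", "wildtype"), each = 20), ids)
  act <- expand.grid(profile = ids, drug = sprintf("d%02d", 1:24),
                     stringsAsFactors = FALSE)
  act$activity <- 2 * scores[act$profile]          # exactly collinear
  res <- drug_response_regression(scores, act, groups)
  expect_equal(attr(res, "bonferroni_threshold"), 0.05 / 48)
  expect_equal(round(attr(res, "bonferroni_threshold"), 3), 0.001)
  expect_equal(nrow(res), 48)
  expect_true(all(res$significant))
  expect_equal(res$r, rep(1, 48), tolerance = 1e-10)
  expect_equal(res$slope, rep(2, 48), tolerance = 1e-10)
})

test_that("independent activity rarely reaches the Bonferroni threshold", {
  set.seed(37)
  ids <- sprintf("c%03d", 1:30)
  groups <- setNames(rep(c("m", "w"), each = 15), ids)
  flags <- replicate(20, {
    scores <- setNames(runif(30), ids)
    act <- expand.grid(profile = ids, drug = sprintf("d%02d", 1:24),
                       stringsAsFactors = FALSE)
    act$activity <- rnorm(nrow(act))
    sum(drug_response_regression(scores, act, groups)$significant)
  })
  expect_lt(mean(flags), 1)
})

test_that("small regression cells are flagged, not fit", {
  ids <- c("c1", "c2", "c3", "c4")
  scores <- setNames(c(0.1, 0.5, 0.9, 0.4), ids)
  groups <- setNames(c("m", "m", "w", "w"), ids)
  act <- data.frame(profile = ids, drug = "dx",
                    activity = c(1, 2, 3, 4))
  res <- drug_response_regression(scores, act, groups)
  expect_true(all(res$flag == "insufficient profiles"))
  expect_true(all(is.na(res$slope)))
})

test_that("multi-hit stratification buckets other-gene events", {
  tg <- gene_targets("KRAS", pathway_genes = c("KRAS", "BRAF", "RAF1", "SOS1",
                                               "PTPN11", "MAP2K1"))
  ids <- sprintf("s%d", 1:6)
  scores <- setNames(c(0.2, 0.4, 0.6, 0.9, 0.3, 0.8), ids)
  muts <- data.frame(
    sample = c("s2", "s3", "s3", "s4", "s4", "s4", "s4", "s4", "s6"),
    gene = c("BRAF", "BRAF", "RAF1", "BRAF", "RAF1", "SOS1", "PTPN11",
             "MAP2K1", "KRAS"),
    variant_class = "Missense_Mutation", stringsAsFactors = FALSE)
  cnv <- matrix(0L, 6, 2, dimnames = list(ids, c("KRAS", "BRAF")))
  res <- multi_hit_stratification(scores, muts, cnv, tg)
  mh <- res$mutation_hits
  expect_identical(mh$bucket[mh$core_status == 0],
                   c("0", "1", "2", "3+"))           # s4 has 5 hits -> 3+
  expect_equal(mh$n[mh$core_status == 0], c(2, 1, 1, 1))
  expect_equal(mh$mean_score[mh$bucket == "3+" & mh$core_status == 0], 0.9)
  # core-positive sample s6 with no other hits
  expect_equal(mh$n[mh$core_status == 1 & mh$bucket == "0"], 1)
  # no copy events outside the core: single bucket per status
  expect_identical(unique(res$copy_hits$bucket), "0")
})

test_that("scores rise with additive other-gene hits among core-negative samples", {
  set.seed(41)
  n <- 200
  ids <- sprintf("s%03d", 1:n)
  hits <- sample(0:4, n, TRUE)
  scores <- setNames(plogis(-1 + 0.8 * hits + rnorm(n, 0, 0.3)), ids)
  muts <- do.call(rbind, lapply(which(hits > 0), function(i)
    data.frame(sample = ids[i], gene = sprintf("P%d", seq_len(hits[i])),
               variant_class = "Missense_Mutation",
               stringsAsFactors = FALSE)))
  cnv <- matrix(0L, n, 1, dimnames = list(ids, "KRAS"))
  tg <- gene_targets("KRAS", pathway_genes = c("KRAS", paste0("P", 1:4)))
  res <- multi_hit_stratification(scores, muts, cnv, tg)
  mh <- res$mutation_hits[res$mutation_hits$core_status == 0, ]
  expect_true(all(diff(mh$mean_score) >= 0))
})
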