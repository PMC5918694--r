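---
title: "Detecting aberrant pathway activity from bulk transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting aberrant pathway activity from bulk transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Tumors can activate a signaling pathway through many different genomic
routes — a hotspot mutation in one of several oncogenes, amplification of
those oncogenes, or loss of a suppressor that restrains the pathway. DNA
sequencing reads out the route; it does not read out whether the pathway is
actually switched on. `pathscore` takes the complementary view: it learns,
from tumors whose alteration status is known, the downstream *expression
state* that aberrant pathway activity produces, and then scores any
expression profile for that state. The canonical application is Ras/MAPK
activation (oncogenes *KRAS*, *NRAS*, *HRAS*; suppressor *NF1*), but the
machinery is generic over any `gene_targets()` specification.

The classifier is a penalized logistic regression. For sample $i$ with
feature vector $X_i$ (standardized expression of selected genes plus
covariates) and binary aberration status $y_i$,

$$P(y_i = 1 \mid X_i) = \frac{1}{1 + e^{-(X_i w + b)}},$$

and the weights minimize the mean negative log-likelihood plus an
elastic-net penalty

$$\hat w = \arg\min_w \; L(w) +
  \alpha \left( l \, \lVert w \rVert_1 +
  \tfrac{1 - l}{2} \lVert w \rVert_2^2 \right),$$

with the intercept $b$ unpenalized. The L1 component produces a sparse,
interpretable gene signature; the L2 component stabilizes correlated
genes. $\alpha$ (overall strength) and $l$ (mixing) are chosen by
stratified 5-fold cross-validation over a fixed grid, maximizing CV AUROC.

Key modeling assumptions, stated plainly:

* **Labels are a usable proxy for pathway activity.** Status is defined
  mechanically — any non-silent mutation in a target gene, a +2
  copy-number threshold call in a target oncogene, or a −2 call in a
  target suppressor. No variant-level oncogenicity curation is applied, so
  some positives are passengers and some negatives are phenocopies
  (aberrations elsewhere that produce the same expression state). The
  evaluation machinery treats phenocopy discovery as signal, not error:
  `cross_gene_eval()` measures exactly this.
* **A shared pan-cancer signature exists.** Cancer-type indicator
  covariates absorb tissue baselines, but the gene weights themselves are
  common to all retained types. `within_type_models()` quantifies what
  this pooling buys or costs per type.
* **Expression enters only through per-gene location and scale.** Gene
  features are standardized, and external datasets are z-scored within
  themselves, so only relative expression shifts matter.

## The labeling and filtering pipeline

`fit_pathway_classifier()` applies the following steps in order; each is
also exported on its own.

1. **Hypermutator removal** (`filter_hypermutators()`). Samples whose
   $\log_{10}(\text{mutation count} + 1)$ exceeds the cohort mean by more
   than 5 SD are removed: extreme-burden tumors hit target genes by chance
   and would contaminate the positive class. The center is the mean and
   zero counts are guarded by the +1; both choices are ours — the
   filtering rule we inherit specifies only the 5-SD offset.
2. **Status construction** (`aberration_status()`). The mutation route
   counts the non-silent classes in `non_silent_classes` (missense,
   nonsense, frameshift and in-frame indels, splice site, nonstop,
   translation start); the copy route counts only the extreme threshold
   calls (±2) — shallow gains and losses never label a sample.
3. **Cancer-type filter** (`filter_cancer_types()`). A type is retained
   when it has strictly more than 15 target-gene events *and* a positive
   fraction of at least 5%. We read the balance rule as a floor on the
   positive *fraction*: the literal alternative (negatives/positives ≥
   5%) is satisfied by almost any cohort and would filter nothing, which
   cannot be the intent of a balance filter. Both thresholds are
   arguments.
4. **Features** (`select_mad_genes()`, `drop_target_genes()`,
   `build_covariates()`, `standardize_features()`). The 8,000 most
   variable genes by median absolute deviation are kept (ties broken
   lexicographically so builds are deterministic), the target genes are
   dropped so the model must learn the downstream response rather than
   target-gene dosage, and the covariate block adds one indicator per
   retained cancer type plus $\log_{10}(\text{count}+1)$ burden. MAD
   ranking is computed *before* dropping targets, so removing a target
   never promotes a lower-MAD replacement into the feature set. All
   indicators are kept (no reference level): the model is penalized, so
   the usual collinearity objection does not apply, and symmetric
   encoding keeps per-type weights comparable. Gene and burden columns
   are standardized with constants estimated on the training partition
   only; indicator columns are left as 0/1. Standardization is our
   addition — it is required for a sanely conditioned SGD problem, and
   the transfer procedure's within-dataset z-scoring shows the weights
   are meant to act on standardized inputs.
5. **Split and search** (`stratified_split()`, `grid_search_cv()`). 10%
   of samples are held out, stratified by cancer type × status; the rest
   get stratified CV folds. Every CV prediction comes from a model that
   never saw that sample. Grid ties break toward smaller $\alpha$, then
   smaller $l$ (the milder, then sparser-but-simpler model).
6. **Final fit.** The model is refit on the full training partition at
   the best cell and evaluated once on the held-out test partition.

## The optimizer

`sgd_elastic_net()` is a proximal stochastic gradient method written for
this package (C++ inner loop):

* one sample per step; the L2 term enters as multiplicative weight decay;
* the L1 term uses cumulative-penalty clipping (Tsuruoka et al. 2009),
  which accumulates the L1 budget across steps and clips weights at zero —
  without it, SGD iterates jitter around zero and the fitted model loses
  its sparsity;
* learning rate $\eta_t = 1 / (L_0 + \alpha(1-l)\,t)$, where
  $L_0 = \tfrac14 \max_i \lVert x_i \rVert^2 + \alpha(1-l)$ bounds the
  per-sample curvature: the schedule starts at the safe deterministic
  step $1/L_0$ and decays at the strong-convexity rate. The unpenalized
  intercept follows its own curvature-based schedule $1/(1 + t/4)$ so a
  large penalty cannot freeze it;
* stopping: up to `max_epochs` (default 100) passes, ending early when
  the full objective changes by less than `tol` (default $10^{-3}$) for
  `patience` (default 5) consecutive epochs;
* sample visiting orders are drawn from R's RNG, so fits are exactly
  reproducible from the configuration seed.

The test suite holds this optimizer to an independent deterministic
proximal-gradient (FISTA) implementation of the same objective — the SGD
objective value must land within 1% of the oracle's on small instances —
and additionally cross-checks against `glmnet`, which fits the same
penalized likelihood by coordinate descent.

Degenerate inputs are handled explicitly: zero-variance features are
dropped with a warning before fitting; cancer-type indicators that are
constant on the training partition (single-type cohorts) are removed
rather than left as a penalized duplicate intercept; CV folds containing a
single class are skipped with a warning; a non-finite objective aborts
with a diagnostic rather than returning garbage.

## Evaluation and benchmarking

`auroc()` is the Mann–Whitney rank form (ties count ½) and is tested
against exhaustive pairwise concordance. `aupr()` is the step-wise
average-precision estimator; we deliberately avoid trapezoidal
interpolation in PR space, which is upward-biased. Note that average
precision itself sits slightly above the positive prevalence for random
rankings at small $n$ — at a 100-sample test partition with 20% positives
the chance level is about 0.23, not 0.20 — which matters when reading
null-model AUPRs off small holdouts.

The benchmarking battery reruns the *entire* pipeline under one change at
a time:

* `shuffled_null()` permutes each gene's values across samples (our
  reading of "shuffled expression": it preserves every gene's marginal
  distribution while destroying sample linkage), leaving labels and
  covariates intact;
* `ablation_battery()` covers mutation-only and copy-only labels,
  retained target genes, the extra 14-gene RASopathy drop
  (`rasopathy_panel`), expression-only and covariate-only features.
  Feature-side ablations share a bit-identical sample partition with the
  full model, and dropped genes are re-inserted as zero weights so
  coefficient vectors align across models;
* `cross_gene_eval()` scores the fitted model against labels built for a
  different gene, optionally excluding the model's own positives;
* `differential_expression()` is the comparison analysis: per-gene OLS of
  zero-one-normalized expression on status plus cancer-type indicators,
  with BH adjustment. We intentionally use ordinary per-gene t-statistics
  rather than empirical-Bayes variance moderation: moderation matters at
  small $n$, and this analysis is meant for cohorts of thousands.

## Transfer to external profiles

`score_external()` z-scores each gene within the external dataset (never
with the training constants — the two datasets are on unrelated scales),
keeps the model's nonzero-weight genes, and applies the logistic
transform. Missing and zero-variance genes contribute nothing; scoring is
refused below 90% gene coverage by default. Covariate terms are omitted:
external profiles carry no cancer-type or burden covariates. Downstream
statistics mirror the published cell-line analysis: `confusion_metrics()`
at threshold 0.5, `aggregate_variant_scores()` at nucleotide or protein
resolution, `enrichment_chi2()` (Pearson, df 1, *no* Yates correction —
the corrected statistic does not reproduce the published value),
`score_group_test()` (Welch), `drug_response_regression()` with the
Bonferroni threshold $0.05/(\text{drugs} \times \text{groups})$, and
`multi_hit_stratification()` with hit buckets 0/1/2/3+.

## What the synthetic cohorts do and do not emulate

`simulate_cohort()` generates the structure the pipeline assumes: several
cancer types with configurable prevalence; truth-level aberration flags; a
planted signature (default 10% of genes shifted by `effect_size` SD in
aberrant samples over standard-normal baselines); mutation or copy
evidence per positive (`copy_fraction` splits the routes); gamma-mixed
Poisson mutation burdens with a hypermutator tail (~50× baseline, ~2% of
samples) whose members acquire chance target-gene mutations at their
genome-scaled background rate — exactly the label noise the hypermutator
filter exists to remove. Spurious target mutations are confined to
hypermutators so that truth and constructed status coincide on filtered
cohorts, which is what makes end-to-end label tests exact.

Deliberately *not* modeled: RNA-seq count distributions (the classifier
standardizes, so only relative shifts matter), gene–gene correlation,
batch effects, realistic mutation spectra, and any dependence between
mutation and copy evidence beyond the shared label. Consequently, passing
tests demonstrate that the machinery is correct and that signal of the
planted kind is recovered; they do not certify performance numbers on
real tumor compendia.

`simulate_external_profiles()` places profiles on an arbitrary per-gene
scale (means near 8, SDs 0.5–2) precisely so that transfer scoring is
exercised through its z-scoring path, with the mutant signature planted
on the same genes.

## Problem sizes and reproducibility

The default simulated conditions are 1,000 samples × 2,000 genes, 20%
prevalence, effect size 1.0 — large enough for the full pipeline
(MAD selection, stratified split, grid CV, held-out evaluation) to behave
as it would at cohort scale while remaining a desk-scale computation. The
test suite uses these at full size for signal-recovery and phenocopy
checks and smaller cohorts (200–600 samples, 50–300 genes) for
contract-level tests; the shuffled-null benchmark in
`scripts/acceptance.R` averages five seeded replicates at the full size.
Every stochastic component — generator, split, fold assignment, SGD
visiting order, shuffles — is driven by explicit seeds, and identical
seeds give bit-identical results.

## Known limitations

* Labels inherit every bias of mechanical status calling; the package
  deliberately performs no oncogenicity curation (annotations pass
  through as metadata only).
* The SGD solution is approximate; the 1% objective band against the
  deterministic oracle is a design target enforced by tests, not a
  convergence proof for arbitrary inputs.
* Hard labels use a fixed 0.5 threshold everywhere; no calibration or
  cost-sensitive thresholding is provided.
* `within_type_models()` optimizes each type on its own small sample and
  can be unstable for rare types — that instability is part of what the
  pan-versus-within comparison is meant to expose.
* Transfer scoring assumes the external dataset is internally homogeneous
  enough for per-gene z-scores to be meaningful; mixed-platform external
  sets should be scored per platform.
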