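---
title: "Methods: TME deconvolution, clustering and the TMEscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TME deconvolution, clustering and the TMEscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `tmescope`: the models
each stage assumes, the parameters that matter, the numerical conventions,
and what the synthetic-cohort generator does and does not emulate.

## Deconvolution model

`estimate_fractions()` treats a bulk expression profile as an approximate
non-negative mixture of reference cell-type profiles. For each sample the
marker-gene vector and the signature matrix are standardized (the signature
by its global mean and SD, the mixture by its own), a linear-kernel
ν-support-vector regression is fit for each ν in a small grid (default
0.25/0.5/0.75, regularization C = 1), and the ν with the lowest
reconstruction RMSE wins. Negative coefficients are truncated at zero and
the remainder renormalized to a simplex. Both the reconstruction and the
mixture are compared on the standardized scale, so a noise-free mixture has
RMSE 0 and the fractions are invariant to a global positive rescaling of the
sample.

Fit significance is a within-sample permutation test: marker values are
shuffled inside the sample, the fit correlation recomputed, and
`p = (1 + #{null ≥ observed}) / (n_perm + 1)`. The ν-SVR solver is
`e1071::svm`; the surrounding algorithm (standardization, ν selection,
truncation, permutation null) is implemented here. Bit-parity with hosted
deconvolution services is not promised; quantile normalization of the
mixture is deliberately not applied. An oracle cross-check against
non-negative least squares (`pracma::lsqnonneg`) runs in the test suite.

## TME subtyping

Clustering operates on the per-sample cell-fraction profiles (LM22-like
width, ~22 features), which are already on a common 0–1 scale; fractions are
therefore not re-scaled by default. Three routes are exposed:

* `hierarchical_cluster()` — Ward's minimum-variance criterion as the
  Lance–Williams "ward.D" update on *squared* Euclidean distances; ties in
  merge cost resolve by the row-order enumeration of `stats::hclust`, so
  results are deterministic given input order (a matrix of identical rows
  still yields a reproducible split).
* `kmeans_cluster()` — k-means++ seeding followed by `stats::kmeans`
  iterations; best of `n_restarts` (default 25) by within-cluster sum of
  squares; deterministic under a fixed seed.
* `consensus_cluster()` — per iteration a fraction (default 0.8) of samples
  is drawn without replacement and clustered; the consensus matrix is
  co-assignments over co-samplings (pairs never co-sampled are reported as
  0 and logged); final labels come from average-linkage clustering of
  1 − consensus. Stability per k is PAC, the share of off-diagonal
  consensus entries strictly inside (0.1, 0.9); the selected k minimizes
  PAC with ties to the smaller k. The consensus-CDF area and its delta are
  emitted for inspection because published consensus analyses usually show
  those plots without naming a selection criterion; PAC is this package's
  explicit rule. Both the subsampled consensus labels and the plain
  hierarchical cut are available — which of the two a study "really" used
  is often unknowable, so neither is hidden.

## Signature genes and modules

`differential_genes()` computes, per gene, a two-sample t statistic with
the pooled variance shrunk toward the cross-gene mean:
`s²_mod = (d₀·s₀² + d·s²)/(d₀ + d)` with a *fixed* prior df `d₀` (default
4) and `p` from a t distribution on `d₀ + d` df. A fixed prior keeps the
estimator self-contained and monotone in the data; an estimated prior df
(as moderated-t packages fit) changes little at the cohort sizes targeted
here. BH adjustment is applied within each contrast.

Two gene summaries are reported on purpose: the **intersection** of
per-contrast significant genes (genes dysregulated in *every* TME
contrast) and the **union** (`signature_pool()`), which feeds the score.
They answer different questions and published gene counts rarely say which
path produced them, so both are first-class outputs.

Modules are K-means clusters of the z-scored signature genes (genes as
objects, samples as features), relabeled so module 1 is largest.
`reduce_by_forest()` ranks genes by out-of-bag permutation importance
(`ranger`, default 500 trees) — more stable than impurity importance — and
keeps the top `floor(keep_fraction · size)` of each module, never emptying
a module; pruning is monotone in `keep_fraction` given the ranking.

## The TMEscore

For each module the z-scored gene block is decomposed by PCA with samples
as observations; the per-sample component score is the projection on PC1
plus PC2. Principal components have an arbitrary sign, so each component is
oriented to correlate non-negatively with the module's mean expression
profile; if that correlation is undefined (constant module mean) the
positive loading sum breaks the tie, and if both fail (e.g. a two-gene
module with correlation exactly −1) the component contributes 0 and a
warning is raised. Components with sd below 1e−10 of PC1's contribute 0; a
single-gene module falls back to the z-scored gene.

Module signs come from univariate Cox fits on the component scores
(Efron ties, Newton–Raphson, relative tolerance 1e−9, ≤ 100 iterations);
|β| < 1e−8 is refused rather than silently signed, and a Wald p > 0.5
triggers an instability warning. Then

`TMEscore = Σ(PC1ᵢ + PC2ᵢ) − Σ(PC1ⱼ + PC2ⱼ)`

over positive-sign modules *i* and negative-sign modules *j*. Note the
orientation consequence: because hazardous (positive-Cox) modules are
*added*, a high TMEscore under this formula tracks higher hazard whenever
the hazardous modules dominate. The package implements the formula as
stated and reports the estimated direction (e.g. via a Cox fit on the
total score) instead of asserting one; the per-sign sub-scores
(`tmescore_pos`/`tmescore_neg`) correspond to the two "sub-score" summaries
often reported alongside such scores, an inference flagged as such.

PCA is computed within each module, not once over the whole signature,
because the formula indexes components by module; a whole-signature variant
can be obtained by passing a single module.

## Survival stratification and response

`maxstat_cutpoint()` evaluates the standardized two-group log-rank
statistic at every observed score value between the 10th and 90th
percentiles and takes the maximizing cutpoint (ties → lower). Because the
maximum ranges over many correlated statistics, the p-value uses the
Miller–Siegmund improved Bonferroni approximation
`p = 4φ(b)/b + φ(b)(b − 1/b)·log[q₂(1−q₁)/(q₁(1−q₂))]` (b = maximal |z|,
(q₁,q₂) the quantile window), with an optional permutation p. The scan is
vectorized over candidates via shared risk-set matrices, so permutation
tests stay cheap. The exhaustive brute-force equivalence (an independent
log-rank per candidate) is asserted in the test suite.

Kaplan–Meier, log-rank and Cox fits delegate to the `survival` package
(product-limit with Greenwood variance; score test; Efron partial
likelihood) behind thin validating wrappers. `roc_auc()` is the
Mann–Whitney concordance probability with 0.5 credit for ties and a DeLong
placement variance. `combine_tmb_score()` fits nested logistic models
(TMB, TMEscore, both), reports the three AUCs and likelihood-ratio tests of
the combined model against each single model; quasi-separation produces a
warning rather than a silent penalized refit. The responder dichotomy is
CR/PR vs SD/PD; four-level score distributions are available from the
clinical table directly.

## Enrichment

`ora()` is the upper-tail hypergeometric test; the universe defaults to
the measured genes, not the union of the collection — this choice changes
p-values materially and is therefore explicit. `gsea_preranked()` is the
running-sum statistic with hit increments ∝ |score|^p (default p = 1;
p = 0 gives the classic Kolmogorov–Smirnov form) and uniform miss
decrements; significance uses gene-set permutation — the only null
available for a preranked input — with `NES = ES / mean(|null ES| of the
same sign)` and smoothed same-sign exceedance p-values.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws, per sample: a latent TME group; cell fractions
from the group's Dirichlet archetype (default 22 cell types in 3 groups,
concentration 8 inside the group's block vs 1 outside — the LM22-like
granularity at which fraction profiles of distinct phenotypes are
geometrically separable); marker expression as the signature-weighted
mixture times lognormal noise (`noise_sd` on the log scale, default 0.1);
planted prognostic modules on the log2 scale as gene baseline + per-sample
module activity (group mean + latent noise, `module_activity_sd` = 0.5,
which is what makes a module a co-expression unit) + gene noise (sd 0.5);
additive per-batch per-gene Gaussian shifts on the log2 scale (the scale
ComBat-style correction operates on); exponential survival with hazard
`baseline_hazard · exp(Σ βₘ · mean module z-expression)` (default 0.02/month,
censoring 0.01/month, β = ±0.8); TMB = max(0, 10 + 4·latent + N(0,2))
mutations/Mb; and CR/PR/SD/PD labels from a proportional-odds model
monotone in the latent score (the negative Cox linear predictor — lower
hazard, better response) with marginal proportions near 10/25/35/30%.
Receptor status is weakly linked to the latent score (ER-positive samples
lean favorable). These defaults are conventions chosen once to be
realistic for the field, not estimates of any specific cohort, whose class
balances and effect sizes are not published.

Not emulated: negative-binomial read counts (values are continuous
TPM-like), probe-level microarray artifacts, paired tumor/normal designs,
informative censoring, and correlated marker noise across genes. Passing
tests therefore demonstrate correctness of the algorithms under the
generative model they assume — not robustness to every pathology of real
cohorts.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use desk-scale sizes chosen for
seconds-to-minutes runtimes: 50 noise-free mixtures for deconvolution,
20-seed clustering recovery at n = 120, 100-seed Cox recovery at n = 500,
20-seed maxstat brute-force comparison at n = 200, and a 20-seed end-to-end
run at n = 600 with a 6-type marker panel. Scale invariances in the
algorithms (standardization, rank statistics) are what justify testing at
these sizes.

Fixed conventions: linear↔log2 conversion is `log2(x + 1)`; z-scoring drops
zero-variance genes with a warning; empirical-Bayes batch correction
delegates to `sva::ComBat` (parametric priors by default) and refuses
single-sample batches; batch correction leaves each gene's grand mean
unchanged only in the vanishing-noise limit — EB shrinkage moves it
slightly under noise, which is inherent to the estimator, not a bug.
Deconvolution requires ≥ 50% marker overlap. All RNG-consuming functions
take a `seed` argument, restore the caller's RNG state, and derive internal
streams from the seed, so no call disturbs global reproducibility.

## Known limitations

* The ν-SVR deconvolution assumes the signature spans the mixture; absent
  cell types inflate the fractions of correlated present ones
  (compositional leakage), as with any simplex-constrained method.
* PAC-based k selection can tie at 0 for nested stable solutions; ties
  resolve to the smaller k by design.
* The maxstat p-value is an asymptotic bound; for small cohorts prefer the
  permutation p (`n_perm`).
* The TMEscore's sign convention is data-driven per cohort; scores are not
  directly comparable across cohorts without a common anchoring of module
  signs.
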