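# tmescope

Characterization of the tumor microenvironment (TME) from bulk expression
data, for transcriptomics analysts who want every stage of a TME-scoring
workflow — deconvolution, subtyping, signature derivation, prognostic
scoring, survival and immunotherapy-response analysis — as plain, tested R
functions rather than a chain of web tools.

## What it computes

Starting from a gene-by-sample expression matrix, a marker signature matrix
(LM22-style: marker genes × immune cell types) and a clinical table:

1. **Deconvolution** — per-sample immune cell fractions by linear-kernel
   ν-support-vector regression of the standardized mixture on the signature
   (negative weights truncated, renormalized to a simplex), with a
   within-sample permutation p-value for fit significance.
2. **TME subtyping** — hierarchical (Ward), K-means++ and subsampled
   consensus clustering of the fraction profiles; the number of groups is
   selected by the proportion of ambiguous clustering (PAC).
3. **Signature genes** — moderated t differential expression across TME
   groups (BH-adjusted), the union of per-contrast significant genes as the
   signature pool (the all-contrast intersection is reported separately),
   K-means gene modules, and random-forest permutation-importance pruning.
4. **TMEscore** — per module, PCA of the z-scored gene block; the
   per-sample component score is the PC1 + PC2 projection; modules are
   signed by the sign of a univariate Cox coefficient, and

   ```
   TMEscore = Σ (PC1_i + PC2_i)  −  Σ (PC1_j + PC2_j)
   ```

   summed over positive-Cox modules *i* and negative-Cox modules *j*.
5. **Stratification & response** — maximally selected rank statistics for
   the high/low cutpoint (with a Miller–Siegmund multiplicity-adjusted p),
   Kaplan–Meier / log-rank / Cox survival analysis, Mann–Whitney AUC with
   DeLong variance, and logistic combination of TMEscore with tumor
   mutational burden (TMB) for responder (CR/PR vs SD/PD) prediction.
6. **Enrichment** — hypergeometric over-representation of gene lists and
   preranked GSEA with a gene-set permutation null.

A seeded synthetic-cohort generator (`simulate_cohort()`) produces
expression, clinical and ground-truth tables with exactly the structure the
pipeline assumes — Dirichlet cell-fraction archetypes pushed through the
signature matrix, planted co-expressed prognostic gene modules with
Cox-linked exponential survival, log-scale batch shifts, TMB and 4-level
response labels — so every stage is verifiable without external downloads.

## Worked example

```r
library(tmescope)

sig    <- make_signature_matrix(6, 10, seed = 1)          # 60 markers x 6 cell types
cfg    <- simulation_config(n_samples = 600, n_cell_types = 6,
                            n_markers_per_type = 10, seed = 42)
cohort <- simulate_cohort(cfg, sig)
res    <- run_tme_pipeline(cohort$expr, cohort$clinical, sig, seed = 42)

res$fractions[1:3, 1:7]
#>  sample_id  CT01  CT02  CT03  CT04  CT05 CT06
#>      S0001 0.395 0.000 0.000 0.539 0.067 0.00
#>      S0002 0.231 0.008 0.000 0.761 0.000 0.00
#>      S0003 0.048 0.358 0.067 0.018 0.459 0.05
```

The recovered TME groups match the planted archetypes exactly
(adjusted Rand index 1), and the signature stage keeps 127 pooled genes
(73 significant in every contrast). The two gene modules get opposite Cox
signs — one hazardous, one protective, as planted:

```r
res$cox_signs
#>    module        beta        hr       wald_p sign
#>  module_1 -0.03356783 0.9669893 8.133373e-07   -1
#>  module_2  0.02925227 1.0296843 2.385711e-02    1

head(res$tmescore[, c("sample_id", "module_1", "module_2", "tmescore", "group")], 3)
#>  sample_id module_1 module_2 tmescore group
#>      S0001    4.376   -3.915   -8.291   low
#>      S0002    3.981   -4.018   -7.999   low
#>      S0003    0.667   -0.303   -0.970  high
```

The maxstat cutpoint (−5.33, standardized log-rank statistic 4.19,
adjusted p = 0.0011) splits the cohort into score groups whose survival
differs strongly (log-rank χ² = 17.5, p = 2.8e−05). Combining the score
with TMB improves responder prediction over TMB alone:

```r
cmb <- combine_tmb_score(cohort$clinical$tmb, res$tmescore$tmescore,
                         cohort$clinical$response)
c(cmb$auc_tmb, cmb$auc_combined)   # 0.685 -> 0.692, LR p = 0.023
```

A thin shell front end over the same functions ships in
`inst/cli/tmescope` (`simulate`, `deconvolve`, `cluster`, `score`,
`enrich` subcommands).

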