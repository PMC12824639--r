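#' Run the full TME characterization pipeline
#'
#' Chains the package's stages on one cohort: cell-fraction deconvolution,
#' TME grouping on the fraction profiles (hierarchical Ward by default),
#' moderated one-vs-rest differential expression across the TME groups,
#' signature pool (union of per-contrast significant genes, with the
#' all-contrast intersection reported separately), gene-module K-means,
#' optional random-forest pruning, per-module PCA component scores,
#' Cox-sign assignment, the TMEscore, a maxstat high/low split, and the
#' log-rank test between the score groups.
#'
#' @param expr expression matrix, genes x samples, linear scale.
#' @param clinical clinical data.frame (sample_id, os_months, os_event, ...).
#' @param sig signature matrix for deconvolution.
#' @param n_tme_groups number of TME groups (default 3).
#' @param n_gene_modules number of gene modules (default 2).
#' @param q_threshold DEG significance threshold (default 0.05).
#' @param forest_keep random-forest keep fraction; NULL skips pruning.
#' @param nu_grid,n_perm passed to [estimate_fractions()].
#' @param cluster_method `"hierarchical"` or `"kmeans"` for TME grouping.
#' @param seed integer seed driving every stochastic stage.
#' @return list: fractions, tme_groups, deg, intersection_genes,
#'   signature_genes, modules, module_scores, cox_signs, tmescore
#'   (data.frame with group and cutpoint columns filled), maxstat, logrank.
#' @export
run_tme_pipeline <- function(expr, clinical, sig,
                             n_tme_groups = 3, n_gene_modules = 2,
                             q_threshold = 0.05, forest_keep = 0.8,
                             nu_grid = c(0.25, 0.5, 0.75), n_perm = 0,
                             cluster_method = c("hierarchical", "kmeans"),
                             seed = 1L) {
  cluster_method <- match.arg(cluster_method)
  clinical <- clinical[match(colnames(expr), clinical$sample_id), ]

  fractions <- estimate_fractions(expr, sig, nu_grid = nu_grid,
                                  n_perm = n_perm, seed = child_seed(seed, 1))
  fr_mat <- as.matrix(fractions[, colnames(sig)])
  rownames(fr_mat) <- fractions$sample_id
  tme_groups <- if (cluster_method == "hierarchical")
    hierarchical_cluster(fr_mat, n_tme_groups)
  else kmeans_cluster(fr_mat, n_tme_groups, seed = child_seed(seed, 2))

  lexpr <- linear_to_log2(expr)
  deg <- differential_genes(lexpr, tme_groups, contrast = "one_vs_rest",
                            q_threshold = q_threshold)
  intersection_genes <- suppressMessages(consistent_genes(deg, q_threshold))
  pool <- signature_pool(deg, q_threshold)
  if (length(pool) < 2 * n_gene_modules)
    stop_invalid("only ", length(pool), " signature genes at q < ", q_threshold,
                 "; too few to form ", n_gene_modules, " modules")

  mz <- zscore_genes(lexpr[pool, , drop = FALSE])
  modules <- cluster_genes(mz, k = n_gene_modules, seed = child_seed(seed, 3))
  if (!is.null(forest_keep) && forest_keep < 1)
    modules <- reduce_by_forest(lexpr, modules, tme_groups,
                                keep_fraction = forest_keep,
                                seed = child_seed(seed, 4))

  scores <- module_score_matrix(mz, modules)
  signs <- assign_cox_signs(scores, clinical$os_months, clinical$os_event)
  score_tab <- compute_tmescore(scores, signs)

  ms <- maxstat_cutpoint(score_tab$tmescore, clinical$os_months, clinical$os_event)
  score_tab$group <- as.character(ms$groups)
  score_tab$cutpoint <- ms$cutpoint
  lr <- logrank_test(clinical$os_months, clinical$os_event, ms$groups)

  list(fractions = fractions, tme_groups = tme_groups, deg = deg,
       intersection_genes = intersection_genes, signature_genes = pool,
       modules = modules, module_scores = scores, cox_signs = signs,
       tmescore = score_tab, maxstat = ms, logrank = lr)
}
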