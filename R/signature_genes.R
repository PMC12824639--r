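#' Moderated differential expression across TME groups
#'
#' Per gene, a two-sample t statistic with the pooled variance shrunk toward
#' the cross-gene mean: `s2_mod = (d0 * s0^2 + d * s2) / (d0 + d)` where
#' `s0^2` is the average pooled gene variance within the contrast, `d` the
#' residual degrees of freedom and `d0` a fixed prior df. P-values use a t
#' distribution on `d0 + d` df and are BH-adjusted within each contrast.
#'
#' @param m expression matrix, genes x samples, log2 scale.
#' @param labels group label per sample (vector aligned with columns, or
#'   named by sample id); every group needs at least 3 samples.
#' @param contrast `"one_vs_rest"` (one contrast per group) or
#'   `"pairwise"` (all group pairs).
#' @param prior_df prior degrees of freedom for variance moderation
#'   (default 4).
#' @param q_threshold significance flag threshold on the BH-adjusted
#'   p-value (default 0.05).
#' @return data.frame with columns gene_id, contrast, effect (mean log2
#'   difference), statistic, p, q, significant.
#' @export
differential_genes <- function(m, labels, contrast = c("one_vs_rest", "pairwise"),
                               prior_df = 4, q_threshold = 0.05) {
  check_expr_matrix(m)
  contrast <- match.arg(contrast)
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  if (length(labels) != ncol(m) || anyNA(labels))
    stop_invalid("every sample needs a group label")
  labels <- factor(labels)
  sizes <- table(labels)
  if (any(sizes < 3))
    stop_invalid("every group needs >= 3 samples; too small: ",
                 paste(names(sizes)[sizes < 3], collapse = ", "))

  one_contrast <- function(a_idx, b_idx, name) {
    na <- length(a_idx); nb <- length(b_idx)
    ma <- rowMeans(m[, a_idx, drop = FALSE])
    mb <- rowMeans(m[, b_idx, drop = FALSE])
    va <- apply(m[, a_idx, drop = FALSE], 1, stats::var)
    vb <- apply(m[, b_idx, drop = FALSE], 1, stats::var)
    d <- na + nb - 2
    s2 <- ((na - 1) * va + (nb - 1) * vb) / d
    s0 <- mean(s2)
    s2_mod <- (prior_df * s0 + d * s2) / (prior_df + d)
    eff <- ma - mb
    tt <- eff / sqrt(s2_mod * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(tt), df = prior_df + d)
    q <- stats::p.adjust(p, method = "BH")
    data.frame(gene_id = rownames(m), contrast = name, effect = eff,
               statistic = tt, p = p, q = q,
               significant = q < q_threshold,
               row.names = NULL, stringsAsFactors = FALSE)
  }

  out <- list()
  if (contrast == "one_vs_rest") {
    for (g in levels(labels))
      out[[g]] <- one_contrast(which(labels == g), which(labels != g),
                               paste0(g, "_vs_rest"))
  } else {
    lv <- levels(labels)
    for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j)
      out[[paste(lv[i], lv[j])]] <-
        one_contrast(which(labels == lv[i]), which(labels == lv[j]),
                     paste0(lv[i], "_vs_", lv[j]))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Genes consistently significant across contrasts
#'
#' Intersection of the genes passing the adjusted-p threshold in every
#' contrast of a differential-expression table. An empty intersection is a
#' valid (logged) outcome, not an error.
#'
#' @param deg data.frame from [differential_genes()] (or rbind of several),
#'   with at least 2 distinct contrasts.
#' @param q_threshold adjusted-p cutoff (default 0.05).
#' @return sorted character vector of gene ids.
#' @export
consistent_genes <- function(deg, q_threshold = 0.05) {
  contrasts <- unique(deg$contrast)
  if (length(contrasts) < 2) stop_invalid("need >= 2 contrasts")
  sig_sets <- lapply(contrasts, function(ct)
    deg$gene_id[deg$contrast == ct & deg$q < q_threshold])
  res <- sort(Reduce(intersect, sig_sets))
  if (length(res) == 0)
    message("no gene significant in every contrast")
  res
}

#' Union of per-contrast significant genes
#'
#' The signature gene pool: every gene significant in at least one contrast.
#' Reported alongside [consistent_genes()] because the two summaries answer
#' different questions (shared dysregulation vs any group signal).
#'
#' @inheritParams consistent_genes
#' @return sorted character vector of gene ids.
#' @export
signature_pool <- function(deg, q_threshold = 0.05) {
  sort(unique(deg$gene_id[deg$q < q_threshold]))
}

#' Cluster signature genes into modules
#'
#' K-means over genes (samples as features) on z-scored expression; module
#' ids are reassigned so module 1 is the largest.
#'
#' @param m_z z-scored expression restricted to signature genes (genes x
#'   samples).
#' @param k number of gene modules (default 2).
#' @param seed integer seed.
#' @return object of class `gene_module_set`: list with `modules` (named
#'   list module_1, module_2, ... of gene ids) and `betas`/`signs` slots
#'   (NULL until [assign_cox_signs()] fills them).
#' @export
cluster_genes <- function(m_z, k = 2, seed = NULL) {
  if (nrow(m_z) < k) stop_invalid("fewer genes than modules requested")
  lab <- kmeans_cluster(m_z, k, seed = seed)
  sizes <- sort(table(lab), decreasing = TRUE)
  modules <- lapply(names(sizes), function(l) sort(names(lab)[lab == l]))
  names(modules) <- paste0("module_", seq_along(modules))
  structure(list(modules = modules, betas = NULL, signs = NULL),
            class = "gene_module_set")
}

#' Prune gene modules by random-forest importance
#'
#' Fits a random-forest classifier of the TME group labels on the module
#' genes' expression, ranks genes by out-of-bag permutation importance, and
#' keeps the top `keep_fraction` of each module (`floor(keep_fraction *
#' size)`, never below 1 gene). Pruning is monotone in `keep_fraction`
#' given the fitted ranking.
#'
#' @param m expression matrix, genes x samples.
#' @param module_set a `gene_module_set`.
#' @param labels group label per sample (>= 2 classes).
#' @param n_trees number of trees (default 500).
#' @param keep_fraction fraction of each module retained, in (0, 1].
#' @param seed integer seed.
#' @return pruned `gene_module_set` with attribute `"importance"` (named
#'   numeric, all genes ranked).
#' @export
reduce_by_forest <- function(m, module_set, labels, n_trees = 500,
                             keep_fraction = 0.8, seed = NULL) {
  if (!inherits(module_set, "gene_module_set")) stop_invalid("module_set must be a gene_module_set")
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop_invalid("keep_fraction must be in (0, 1]")
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  y <- factor(labels)
  if (nlevels(y) < 2) stop_invalid("need >= 2 classes to rank genes")
  genes <- unlist(module_set$modules, use.names = FALSE)
  x <- t(m[genes, , drop = FALSE])
  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                        importance = "permutation",
                        seed = if (is.null(seed)) 1L else as.integer(seed))
  imp <- fit$variable.importance[genes]
  pruned <- lapply(module_set$modules, function(gs) {
    keep_n <- max(1L, floor(keep_fraction * length(gs)))
    ord <- gs[order(-imp[gs], gs)]
    sort(ord[seq_len(keep_n)])
  })
  structure(list(modules = pruned, betas = NULL, signs = NULL),
            class = "gene_module_set", importance = imp)
}
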