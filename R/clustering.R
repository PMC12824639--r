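#' Hierarchical Ward clustering of samples
#'
#' Agglomerative clustering with Ward's minimum-variance criterion applied
#' to squared Euclidean distances (the Lance-Williams "ward.D" update on
#' squared distances), tree cut to exactly `k` groups. Deterministic given
#' the input row order; equal merge costs are resolved by the agglomeration
#' order of [stats::hclust()], i.e. the pair appearing first in
#' lexicographic (row-order) enumeration merges first.
#'
#' @param x numeric matrix, samples x features.
#' @param k number of clusters, `2 <= k < nrow(x)`.
#' @return integer cluster labels (1..k) named by the rownames of `x`.
#' @export
hierarchical_cluster <- function(x, k) {
  x <- as.matrix(x)
  if (k < 2 || k >= nrow(x)) stop_invalid("need 2 <= k < number of samples")
  hc <- stats::hclust(stats::dist(x)^2, method = "ward.D")
  stats::cutree(hc, k = k)
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) {
      idx[i] <- sample.int(n, 1)
    } else {
      idx[i] <- sample.int(n, 1, prob = d2)
    }
    di <- rowSums((x - matrix(x[idx[i], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, di)
  }
  x[idx, , drop = FALSE]
}

#' K-means clustering with k-means++ restarts
#'
#' Runs [stats::kmeans()] from `n_restarts` k-means++ initializations and
#' keeps the solution with the lowest within-cluster sum of squares.
#' Deterministic under a fixed seed.
#'
#' @param x numeric matrix, samples x features (or genes x samples for gene
#'   clustering; rows are the objects clustered).
#' @param k number of clusters, at least 2 and below `nrow(x)`.
#' @param n_restarts independent initializations (default 25).
#' @param seed integer seed.
#' @return integer labels (1..k) named by rownames of `x`, with attribute
#'   `"wcss"` holding the winning within-cluster sum of squares.
#' @export
kmeans_cluster <- function(x, k, n_restarts = 25, seed = NULL) {
  x <- as.matrix(x)
  if (k < 2 || k >= nrow(x)) stop_invalid("need 2 <= k < number of objects")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_centers(x, k)
      if (anyDuplicated(centers)) centers <- centers +
          matrix(stats::rnorm(length(centers), 0, 1e-8), nrow(centers))
      fit <- tryCatch(stats::kmeans(x, centers = centers, iter.max = 100),
                      error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop_invalid("k-means failed for every restart")
    labels <- best$cluster
    names(labels) <- rownames(x)
    attr(labels, "wcss") <- best$tot.withinss
    labels
  })
}

#' Subsampled consensus clustering with PAC-based k selection
#'
#' For each candidate `k`, repeatedly subsamples the cohort without
#' replacement, clusters the subsample with the base method, and records how
#' often each sample pair lands in the same cluster relative to how often it
#' was co-sampled. Final labels come from average-linkage hierarchical
#' clustering of `1 - consensus`. Stability per `k` is the proportion of
#' ambiguous clustering (PAC): the fraction of off-diagonal consensus
#' entries strictly inside `pac_window`. The selected `k` minimizes PAC,
#' ties going to the smaller `k`. The area under the consensus CDF and its
#' relative increase (delta area) are also reported for inspection.
#'
#' @param x numeric matrix, samples x features.
#' @param k_range integer vector of candidate cluster numbers (each >= 2).
#' @param n_iter subsampling iterations per k (default 1000).
#' @param subsample_fraction fraction of samples drawn per iteration, in (0, 1].
#' @param base `"hierarchical"` (Ward) or `"kmeans"`.
#' @param pac_window ambiguity interval (default `c(0.1, 0.9)`).
#' @param seed integer seed.
#' @return list with `selected_k`, and `results`: one entry per k holding
#'   `k`, `consensus_matrix`, `labels`, `pac`, `cdf_area`, `delta_area`,
#'   `n_iter`, `n_skipped`, `subsample_fraction`.
#' @export
consensus_cluster <- function(x, k_range, n_iter = 1000, subsample_fraction = 0.8,
                              base = c("hierarchical", "kmeans"),
                              pac_window = c(0.1, 0.9), seed = NULL) {
  x <- as.matrix(x)
  base <- match.arg(base)
  if (any(k_range < 2)) stop_invalid("every k must be >= 2")
  if (n_iter < 2) stop_invalid("n_iter must be >= 2")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop_invalid("subsample_fraction must be in (0, 1]")
  n <- nrow(x)
  m_sub <- max(2L, floor(subsample_fraction * n))
  sample_ids <- rownames(x)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))

  results <- list()
  for (k in sort(unique(as.integer(k_range)))) {
    I <- matrix(0, n, n)  # co-assignment counts
    S <- matrix(0, n, n)  # co-sampling counts
    skipped <- 0L
    with_seed(child_seed(seed, k), {
      for (it in seq_len(n_iter)) {
        idx <- if (m_sub == n) seq_len(n) else sort(sample.int(n, m_sub))
        if (m_sub <= k) { skipped <- skipped + 1L; next }
        lab <- tryCatch(
          if (base == "hierarchical") hierarchical_cluster(x[idx, , drop = FALSE], k)
          else kmeans_cluster(x[idx, , drop = FALSE], k, n_restarts = 3,
                              seed = NULL),
          error = function(e) NULL)
        if (is.null(lab) || length(unique(lab)) < k) { skipped <- skipped + 1L; next }
        ind <- outer(lab, seq_len(k), "==") + 0
        I[idx, idx] <- I[idx, idx] + tcrossprod(ind)
        S[idx, idx] <- S[idx, idx] + 1
      }
    })
    if (skipped > 0.1 * n_iter)
      warning(skipped, "/", n_iter, " iterations skipped for k = ", k)
    never <- S == 0 & upper.tri(S)
    if (any(never))
      message(sum(never), " sample pair(s) never co-sampled at k = ", k,
              "; their consensus is reported as 0")
    cm <- ifelse(S > 0, I / pmax(S, 1), 0)
    cm <- (cm + t(cm)) / 2
    diag(cm) <- 1
    dimnames(cm) <- list(sample_ids, sample_ids)
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    labels <- stats::cutree(hc, k = k)
    ut <- cm[upper.tri(cm)]
    pac <- mean(ut > pac_window[1] & ut < pac_window[2])
    results[[as.character(k)]] <- list(k = k, consensus_matrix = cm,
                                       labels = labels, pac = pac,
                                       cdf_area = mean(1 - ut),
                                       delta_area = NA_real_,
                                       n_iter = n_iter, n_skipped = skipped,
                                       subsample_fraction = subsample_fraction)
  }
  ks <- as.integer(names(results))
  areas <- vapply(results, function(r) r$cdf_area, 1.0)
  for (i in seq_along(ks))
    results[[i]]$delta_area <- if (i == 1) areas[1] else
      (areas[i] - areas[i - 1]) / max(areas[i - 1], .Machine$double.eps)
  pacs <- vapply(results, function(r) r$pac, 1.0)
  selected_k <- ks[which.min(pacs)]  # which.min takes the first, i.e. smallest k
  list(selected_k = selected_k, results = results)
}
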