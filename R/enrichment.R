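#' Over-representation analysis by the hypergeometric test
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap when `n = |list|` genes are sampled from a
#' universe of `N` genes containing `K = |set intersect universe|` set
#' members. Sets are intersected with the universe first; sets left empty
#' are omitted with a warning. Q-values are BH-adjusted across the tested
#' sets. The universe should be the genes actually measured (e.g. all rows
#' of the expression matrix), not the union of the collection — the choice
#' changes p-values materially.
#'
#' @param genes character vector, the gene list of interest (must be a
#'   subset of `universe`).
#' @param universe character vector of all eligible genes.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @return data.frame: set_id, set_size (K), overlap, expected, p, q.
#' @export
ora <- function(genes, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_invalid("empty universe")
  if (!all(genes %in% universe))
    stop_invalid("gene list contains genes outside the universe: ",
                 paste(utils::head(setdiff(genes, universe), 5), collapse = ", "))
  genes <- unique(genes)
  N <- length(universe); n <- length(genes)
  rows <- lapply(names(sets), function(id) {
    K_genes <- intersect(sets[[id]], universe)
    if (length(K_genes) == 0) return(NULL)
    K <- length(K_genes)
    ov <- length(intersect(genes, K_genes))
    data.frame(set_id = id, set_size = K, overlap = ov,
               expected = n * K / N,
               p = stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  dropped <- names(sets)[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    warning("set(s) disjoint from the universe omitted: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

# Running-sum enrichment score of one set against a ranked score vector.
# Hit increments proportional to |score|^p, miss decrements uniform.
gsea_es <- function(ord_scores, hit, weight_p) {
  N <- length(ord_scores); K <- sum(hit)
  inc <- abs(ord_scores)^weight_p * hit
  if (sum(inc) == 0) inc <- hit + 0  # all-zero hit scores: unweighted
  inc <- inc / sum(inc)
  dec <- (1 - hit) / (N - K)
  run <- cumsum(inc - dec)
  unname(run[which.max(abs(run))])
}

#' Preranked gene-set enrichment analysis
#'
#' Genes are ordered by decreasing score; the running sum increments at set
#' members (proportionally to |score|^`weight_p`) and decrements uniformly
#' elsewhere. ES is the signed extremum of the running sum. Significance
#' comes from a gene-set permutation null (random sets of the same size
#' drawn from the ranking): `NES = ES / mean(|null ES| of the same sign)`,
#' and the p-value is the smoothed same-sign exceedance fraction
#' `(1 + #exceed) / (1 + #same-sign nulls)`. Q-values are BH-adjusted
#' across sets. Sets overlapping the ranking in fewer than 2 genes are
#' skipped with a warning.
#'
#' @param scores named numeric vector of ranking scores (no duplicate
#'   gene names); sign carries direction.
#' @param sets named list of gene sets, or a single character vector.
#' @param weight_p hit-weight exponent (default 1; 0 gives the classic
#'   Kolmogorov-Smirnov statistic).
#' @param n_perm number of set-label permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame: set_id, size (overlap with ranking), es, nes, p, q,
#'   direction ("up"/"down").
#' @export
gsea_preranked <- function(scores, sets, weight_p = 1, n_perm = 1000, seed = NULL) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop_invalid("scores must be named by unique gene ids")
  if (!is.list(sets)) sets <- list(set = sets)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  genes <- names(s)
  N <- length(genes)

  rows <- with_seed(seed, {
    out <- list()
    for (id in names(sets)) {
      hit <- as.numeric(genes %in% sets[[id]])
      K <- sum(hit)
      if (K < 2) {
        warning("set '", id, "' overlaps the ranking in < 2 genes; skipped")
        next
      }
      es <- gsea_es(s, hit, weight_p)
      null_es <- vapply(seq_len(n_perm), function(i) {
        h <- numeric(N); h[sample.int(N, K)] <- 1
        gsea_es(s, h, weight_p)
      }, 1.0)
      same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      out[[id]] <- data.frame(set_id = id, size = K, es = es, nes = nes,
                              p = p, direction = if (es >= 0) "up" else "down",
                              stringsAsFactors = FALSE)
    }
    out
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(res)) return(NULL)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}
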