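#' Convert FPKM-scale expression to TPM
#'
#' Per sample, divides each gene's FPKM by the sample's total and rescales
#' to one million, so every column sums to 1e6. Applying the conversion
#' twice is the same as applying it once.
#'
#' @param m numeric matrix, genes x samples, linear (FPKM-like) scale.
#' @return matrix of the same dimensions on the TPM scale.
#' @export
fpkm_to_tpm <- function(m) {
  check_expr_matrix(m)
  if (any(m < 0)) stop_invalid("linear-scale expression must be non-negative")
  tot <- colSums(m)
  bad <- tot <= 0
  if (any(bad))
    stop_invalid("sample(s) with all-zero expression: ",
                 paste(colnames(m)[bad], collapse = ", "))
  sweep(m, 2, tot, "/") * 1e6
}

#' Z-score genes across samples
#'
#' Centers and scales every gene row to mean 0 and sample standard deviation
#' 1. Zero-variance genes cannot be scaled and are dropped with a warning.
#'
#' @param m numeric matrix, genes x samples, at least 2 samples.
#' @return matrix of z-scores; possibly fewer rows than the input.
#' @export
zscore_genes <- function(m) {
  check_expr_matrix(m)
  if (ncol(m) < 2) stop_invalid("z-scoring needs at least 2 samples")
  sds <- apply(m, 1, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning(sum(drop), " zero-variance gene(s) dropped during z-scoring")
    m <- m[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  (m - rowMeans(m)) / sds
}

#' Convert between linear and log2 expression scales
#'
#' Uses the fixed offset log2(x + 1); `log2_to_linear` inverts it.
#'
#' @param m numeric matrix.
#' @return matrix on the other scale.
#' @export
linear_to_log2 <- function(m) {
  if (any(m < 0)) stop_invalid("linear-scale expression must be non-negative")
  log2(m + 1)
}

#' @rdname linear_to_log2
#' @export
log2_to_linear <- function(m) pmax(2^m - 1, 0)

#' Remove additive batch effects by empirical Bayes
#'
#' Location-scale batch correction on log2-scale expression via
#' [sva::ComBat()]: per gene and batch, batch means and variances are
#' estimated, shrunk toward cross-gene priors by empirical Bayes
#' (`parametric = TRUE` uses the normal / inverse-gamma parametric priors),
#' removed, and the pooled moments restored. A single-batch matrix is
#' returned unchanged with a warning.
#'
#' @param m numeric matrix, genes x samples, log2 scale.
#' @param batch character or factor batch label per sample (recycled names
#'   must match `colnames(m)` if named).
#' @param parametric use parametric empirical-Bayes priors (default TRUE).
#' @return corrected matrix, same dimensions as `m`.
#' @export
correct_batches <- function(m, batch, parametric = TRUE) {
  check_expr_matrix(m)
  if (!is.null(names(batch))) batch <- batch[colnames(m)]
  if (length(batch) != ncol(m) || anyNA(batch))
    stop_invalid("every sample needs a batch label")
  batch <- factor(batch)
  if (nlevels(batch) < 2) {
    warning("single batch: nothing to correct, returning input unchanged")
    return(m)
  }
  sizes <- table(batch)
  if (any(sizes < 2))
    stop_invalid("batch(es) with a single sample cannot be corrected: ",
                 paste(names(sizes)[sizes < 2], collapse = ", "),
                 "; merge or drop them first")
  # ComBat cannot shrink variance for genes that are constant within a batch
  out <- m
  v_ok <- apply(m, 1, function(x) all(tapply(x, batch, stats::var) > 0))
  v_ok[is.na(v_ok)] <- FALSE
  if (!all(v_ok))
    warning(sum(!v_ok), " gene(s) constant within a batch left uncorrected")
  if (any(v_ok))
    out[v_ok, ] <- suppressMessages(
      sva::ComBat(dat = m[v_ok, , drop = FALSE], batch = batch,
                  par.prior = parametric, prior.plots = FALSE))
  out
}
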