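#' Build a synthetic marker signature matrix
#'
#' Constructs a marker-gene-by-cell-type reference matrix with the structure
#' of immune deconvolution signatures such as LM22: each cell type owns a
#' block of marker genes whose expression in that type exceeds its expression
#' in every other type by at least `fold`. Values are on a linear
#' (TPM-like) scale and strictly positive.
#'
#' @param n_cell_types number of cell types (columns), at least 2.
#' @param n_markers_per_type markers per cell type (rows per block), at least 1.
#' @param fold minimum dominance fold of a marker in its own type (default 8).
#' @param seed integer seed; the same seed reproduces the same matrix.
#' @return numeric matrix of size `n_cell_types * n_markers_per_type` rows by
#'   `n_cell_types` columns, with unique row and column names.
#' @examples
#' sig <- make_signature_matrix(4, 10, seed = 1)
#' dim(sig)
#' @export
make_signature_matrix <- function(n_cell_types, n_markers_per_type,
                                  fold = 8, seed = NULL) {
  if (!is.numeric(n_cell_types) || n_cell_types < 2)
    stop_invalid("n_cell_types must be >= 2")
  if (!is.numeric(n_markers_per_type) || n_markers_per_type < 1)
    stop_invalid("n_markers_per_type must be >= 1")
  if (fold <= 1) stop_invalid("fold must exceed 1")
  n_cell_types <- as.integer(n_cell_types)
  n_markers_per_type <- as.integer(n_markers_per_type)
  with_seed(seed, {
    types <- sprintf("CT%02d", seq_len(n_cell_types))
    n_genes <- n_cell_types * n_markers_per_type
    sig <- matrix(stats::runif(n_genes * n_cell_types, 0.5, 1.5),
                  n_genes, n_cell_types)
    rn <- character(n_genes)
    for (t in seq_len(n_cell_types)) {
      rows <- (t - 1L) * n_markers_per_type + seq_len(n_markers_per_type)
      # own-type expression strictly dominates the row max elsewhere
      off_max <- apply(sig[rows, -t, drop = FALSE], 1, max)
      sig[rows, t] <- off_max * fold * stats::runif(length(rows), 1.05, 1.5)
      rn[rows] <- sprintf("MK_%s_%03d", types[t], seq_len(n_markers_per_type))
    }
    dimnames(sig) <- list(rn, types)
    sig
  })
}
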