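# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' `.Random.seed`, so seeded operations never disturb global RNG state.
#' A `NULL` seed runs `expr` under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, staying below
# 2^31 so the result is a valid R integer.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% 2147483647)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_expr_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m))
    stop_invalid(arg, " must be a numeric matrix (genes in rows, samples in columns)")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop_invalid(arg, " must have unique row (gene) names")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop_invalid(arg, " must have unique column (sample) names")
  if (any(!is.finite(m)))
    stop_invalid(arg, " contains non-finite values")
  invisible(m)
}

# Dirichlet draws via normalized gamma variates; zero concentrations give
# exact zeros (degenerate vertices are allowed on purpose).
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(0, n, k)
  pos <- alpha > 0
  x[, pos] <- matrix(stats::rgamma(n * sum(pos), shape = rep(alpha[pos], each = n)),
                     n, sum(pos))
  sw <- rowSums(x)
  if (any(sw == 0)) x[sw == 0, which(pos)[1]] <- 1
  x / rowSums(x)
}
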