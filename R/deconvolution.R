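#' Estimate immune cell-type fractions by nu-support-vector regression
#'
#' CIBERSORT-style deconvolution: each bulk sample is regressed on the
#' reference signature matrix with a linear-kernel nu-SVR over a small grid
#' of nu values; the fit with the lowest reconstruction RMSE is kept,
#' negative coefficients are truncated at zero and the rest normalized to
#' fractions summing to one. Standardization is per call: the signature is
#' centered/scaled by its global mean and SD, each mixture column by its own
#' mean and SD, which makes the fractions invariant to a global positive
#' rescaling of a sample. Significance comes from a permutation null in
#' which the sample's marker values are shuffled (within sample) and the fit
#' correlation recomputed.
#'
#' @param m expression matrix, genes x samples, linear or log2 scale
#'   (standardization makes the fit scale-tolerant; linear TPM-like input is
#'   the convention).
#' @param sig signature matrix, marker genes x cell types.
#' @param nu_grid nu values to try (default 0.25/0.5/0.75, the CIBERSORT grid).
#' @param n_perm permutations for the p-value (0 skips it; the reference
#'   method uses 1000).
#' @param seed integer seed for the permutation null.
#' @return data.frame with one row per sample: estimated fraction per cell
#'   type, `fit_correlation`, `fit_rmse` (standardized scale) and
#'   `perm_pvalue` (NA when `n_perm = 0`). Fractions are non-negative and
#'   sum to 1.
#' @export
estimate_fractions <- function(m, sig, nu_grid = c(0.25, 0.5, 0.75),
                               n_perm = 0, seed = NULL) {
  check_expr_matrix(m)
  if (!is.matrix(sig) || ncol(sig) < 2) stop_invalid("signature needs >= 2 cell types")
  if (length(nu_grid) < 1) stop_invalid("nu_grid must be non-empty")
  shared <- intersect(rownames(sig), rownames(m))
  if (length(shared) < 0.5 * nrow(sig)) {
    missing <- setdiff(rownames(sig), rownames(m))
    stop_invalid("only ", length(shared), "/", nrow(sig),
                 " signature markers found in the mixture; missing: ",
                 paste(utils::head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) ", ...")
  }
  X <- sig[shared, , drop = FALSE]
  Xs <- (X - mean(X)) / stats::sd(X)
  Y <- m[shared, , drop = FALSE]

  fit_one <- function(y) {
    best <- NULL
    for (nu in nu_grid) {
      fit <- e1071::svm(Xs, y, type = "nu-regression", kernel = "linear",
                        nu = nu, cost = 1, scale = FALSE)
      w <- drop(t(fit$coefs) %*% fit$SV)
      w[w < 0] <- 0
      if (sum(w) == 0) { frac <- rep(1 / ncol(Xs), ncol(Xs)) } else frac <- w / sum(w)
      recon <- drop(Xs %*% frac)
      # compare on a common standardized scale: a perfect mixture then has
      # rmse 0 because standardization absorbs the affine mismatch
      rs <- if (stats::sd(recon) > 0) (recon - mean(recon)) / stats::sd(recon)
            else recon - mean(recon)
      rmse <- sqrt(mean((rs - y)^2))
      if (is.null(best) || rmse < best$rmse)
        best <- list(frac = frac, rmse = rmse, corr = stats::cor(recon, y))
    }
    best
  }

  res <- matrix(NA_real_, ncol(Y), ncol(X),
                dimnames = list(colnames(Y), colnames(X)))
  corr <- rmse <- pval <- rep(NA_real_, ncol(Y))
  perm_seed <- child_seed(seed, 1L)
  for (j in seq_len(ncol(Y))) {
    yraw <- Y[, j]
    if (stats::sd(yraw) == 0)
      stop_invalid("sample ", colnames(Y)[j], " has zero variance across markers")
    y <- (yraw - mean(yraw)) / stats::sd(yraw)
    b <- fit_one(y)
    res[j, ] <- b$frac; corr[j] <- b$corr; rmse[j] <- b$rmse
    if (n_perm > 0) {
      exceed <- with_seed(child_seed(perm_seed, j), {
        sum(vapply(seq_len(n_perm), function(i) {
          fit_one(sample(y))$corr >= b$corr
        }, logical(1)))
      })
      pval[j] <- (exceed + 1) / (n_perm + 1)
    }
  }
  out <- data.frame(sample_id = rownames(res), res,
                    fit_correlation = corr, fit_rmse = rmse,
                    perm_pvalue = pval,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Goodness of fit of a deconvolution result
#'
#' Recomputes, per sample, the Pearson correlation and standardized-scale
#' RMSE between the observed marker vector and its reconstruction from the
#' estimated fractions.
#'
#' @param m expression matrix used for the fit.
#' @param sig signature matrix used for the fit.
#' @param fractions data.frame from [estimate_fractions()] (or any table
#'   with `sample_id` and one column per cell type of `sig`).
#' @return data.frame: sample_id, correlation, rmse.
#' @export
goodness_of_fit <- function(m, sig, fractions) {
  shared <- intersect(rownames(sig), rownames(m))
  Xs <- (sig[shared, ] - mean(sig[shared, ])) / stats::sd(sig[shared, ])
  unknown <- setdiff(fractions$sample_id, colnames(m))
  if (length(unknown))
    stop_invalid("unknown sample(s): ", paste(unknown, collapse = ", "))
  out <- lapply(seq_len(nrow(fractions)), function(i) {
    sid <- fractions$sample_id[i]
    y <- m[shared, sid]
    y <- (y - mean(y)) / stats::sd(y)
    recon <- drop(Xs %*% as.numeric(fractions[i, colnames(sig)]))
    rs <- if (stats::sd(recon) > 0) (recon - mean(recon)) / stats::sd(recon)
          else recon - mean(recon)
    data.frame(sample_id = sid,
               correlation = stats::cor(y, recon),
               rmse = sqrt(mean((y - rs)^2)))
  })
  do.call(rbind, out)
}
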