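#' Per-sample PCA component score of one gene module
#'
#' PCA of the module's z-scored gene-by-sample block with samples as
#' observations; the per-sample component score is the projection on PC1
#' plus the projection on PC2. Principal components have a sign
#' indeterminacy, so each retained component is oriented to correlate
#' non-negatively with the module's mean expression profile across samples;
#' when that correlation is undefined (constant module mean) the positive
#' loading sum breaks the tie, and when both conventions fail the component
#' is dropped (contributes 0) with a warning. Components with negligible
#' variance (sd below 1e-10 of PC1's) contribute 0. A single-gene module
#' falls back to the z-scored gene itself, with a message.
#'
#' @param m_z z-scored expression matrix (genes x samples).
#' @param genes gene ids of the module (>= 1, present in `m_z`).
#' @return named numeric vector: per-sample PC1 + PC2 score.
#' @export
module_pc_scores <- function(m_z, genes) {
  missing <- setdiff(genes, rownames(m_z))
  if (length(missing))
    stop_invalid("module gene(s) absent from matrix: ",
                 paste(utils::head(missing, 5), collapse = ", "))
  if (ncol(m_z) < 3) stop_invalid("need >= 3 samples for module PCA")
  block <- m_z[genes, , drop = FALSE]
  if (length(genes) == 1) {
    message("single-gene module: using the z-scored gene as its score")
    return(drop(block))
  }
  pc <- stats::prcomp(t(block), center = TRUE, scale. = FALSE)
  mmean <- colMeans(block)
  total <- rep(0, ncol(m_z))
  n_comp <- min(2L, ncol(pc$x))
  for (i in seq_len(n_comp)) {
    if (pc$sdev[i] < 1e-10 * max(pc$sdev[1], .Machine$double.eps)) next
    sc <- pc$x[, i]
    r <- suppressWarnings(stats::cor(sc, mmean))
    if (is.finite(r) && abs(r) > 1e-12) {
      if (r < 0) sc <- -sc
    } else {
      ls <- sum(pc$rotation[, i])
      if (abs(ls) > 1e-12) {
        if (ls < 0) sc <- -sc
      } else {
        warning("component ", i, " orientation undefined for this module; ",
                "it contributes 0 to the score")
        next
      }
    }
    total <- total + sc
  }
  stats::setNames(total, colnames(m_z))
}

#' Component-score matrix for a module set
#'
#' Convenience wrapper running [module_pc_scores()] for every module.
#'
#' @param m_z z-scored expression matrix.
#' @param module_set a `gene_module_set` (or plain named list of gene ids).
#' @return numeric matrix, samples x modules.
#' @export
module_score_matrix <- function(m_z, module_set) {
  modules <- if (inherits(module_set, "gene_module_set")) module_set$modules else module_set
  out <- vapply(modules, function(gs) module_pc_scores(m_z, gs),
                numeric(ncol(m_z)))
  rownames(out) <- colnames(m_z)
  out
}

#' Assign Cox-coefficient signs to gene modules
#'
#' Fits a univariate Cox proportional-hazards model of survival on each
#' module's component score and records the sign of the estimated
#' log-hazard coefficient. A coefficient indistinguishable from zero
#' (|beta| < 1e-8) is refused — the module's direction must then be set
#' manually. A Wald p-value above 0.5 triggers an instability warning.
#'
#' @param scores samples x modules matrix from [module_score_matrix()].
#' @param times,events survival times (months) and 0/1 event indicators,
#'   aligned with the rows of `scores`; at least 10 events.
#' @return data.frame: module, beta, hr, wald_p, sign.
#' @export
assign_cox_signs <- function(scores, times, events) {
  if (sum(events) < 1) stop_invalid("no events: cannot estimate Cox signs")
  if (sum(events) < 10) stop_invalid("need >= 10 events to estimate Cox signs")
  res <- lapply(colnames(scores), function(mod) {
    fit <- survival::coxph(survival::Surv(times, events) ~ scores[, mod],
                           ties = "efron",
                           control = survival::coxph.control(eps = 1e-9, iter.max = 100))
    beta <- unname(stats::coef(fit))
    p <- summary(fit)$coefficients[1, "Pr(>|z|)"]
    if (abs(beta) < 1e-8)
      stop_invalid("module ", mod, ": |beta| < 1e-8, sign undetermined; ",
                   "assign the module's direction manually")
    if (p > 0.5)
      warning("module ", mod, ": Cox sign unstable (Wald p = ",
              signif(p, 2), ")")
    data.frame(module = mod, beta = beta, hr = exp(beta), wald_p = p,
               sign = sign(beta), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compute the per-sample TMEscore
#'
#' `TMEscore = sum(PC1 + PC2 over modules with positive Cox sign) -
#' sum(PC1 + PC2 over modules with negative Cox sign)`. The two sums are
#' also reported separately as `tmescore_pos` and `tmescore_neg`.
#'
#' @param scores samples x modules component matrix.
#' @param signs named vector of +1/-1 per module, or the data.frame from
#'   [assign_cox_signs()].
#' @return data.frame: sample_id, one column per module component,
#'   tmescore_pos, tmescore_neg, tmescore.
#' @export
compute_tmescore <- function(scores, signs) {
  if (is.data.frame(signs)) signs <- stats::setNames(signs$sign, signs$module)
  missing <- setdiff(colnames(scores), names(signs))
  if (length(missing))
    stop_invalid("no sign for module(s): ", paste(missing, collapse = ", "))
  signs <- signs[colnames(scores)]
  if (!all(signs %in% c(-1, 1))) stop_invalid("signs must be +1 or -1")
  pos <- colnames(scores)[signs > 0]
  neg <- colnames(scores)[signs < 0]
  tp <- if (length(pos)) rowSums(scores[, pos, drop = FALSE]) else rep(0, nrow(scores))
  tn <- if (length(neg)) rowSums(scores[, neg, drop = FALSE]) else rep(0, nrow(scores))
  data.frame(sample_id = rownames(scores), scores,
             tmescore_pos = tp, tmescore_neg = tn, tmescore = tp - tn,
             check.names = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}

# Standardized two-group log-rank statistic (group = score > cutpoint).
# Observed-minus-expected over event times with hypergeometric variance.
logrank_z_stat <- function(times, events, in_high) {
  ev_times <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_high)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & in_high)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(NA_real_)
  (O - E) / sqrt(V)
}

# Standardized log-rank statistics for every candidate cutpoint at once.
# H is a samples x candidates indicator of membership in the 'high' group;
# risk sets and event counts are shared across candidates, so the whole
# scan reduces to two matrix products.
logrank_z_scan <- function(times, events, H) {
  te <- sort(unique(times[events == 1]))
  R <- outer(te, times, function(t, x) as.numeric(x >= t))   # at risk
  Dm <- outer(te, times, function(t, x) as.numeric(x == t)) *
    matrix(events, length(te), length(times), byrow = TRUE)  # event at t
  n_t <- rowSums(R)
  d_t <- rowSums(Dm)
  n1 <- R %*% H
  d1 <- Dm %*% H
  O <- colSums(d1)
  E <- colSums(d_t * n1 / n_t)
  vt <- ifelse(n_t > 1, d_t * (n_t - d_t) / (n_t^2 * (n_t - 1)), 0)
  V <- colSums(vt * n1 * (n_t - n1))
  z <- (O - E) / sqrt(V)
  z[V <= 0] <- NA_real_
  z
}

#' Optimal survival cutpoint by maximally selected rank statistics
#'
#' Evaluates the standardized two-group log-rank statistic at every
#' observed score value inside the quantile window and selects the cutpoint
#' maximizing its absolute value (ties go to the lower cutpoint). Because
#' the maximum is taken over many correlated statistics, the p-value uses
#' the Miller-Siegmund improved Bonferroni approximation
#' `p = 4 * phi(b) / b + phi(b) * (b - 1/b) * log(q2 (1 - q1) / (q1 (1 - q2)))`
#' where `b` is the maximal |statistic| and `(q1, q2)` the quantile window;
#' an optional permutation p-value (shuffling scores against survival) is
#' available via `n_perm`.
#'
#' @param score numeric score per sample.
#' @param times,events survival times and 0/1 event indicators.
#' @param quantile_window candidate cutpoints are restricted to scores
#'   between these quantiles (default 0.1–0.9).
#' @param n_perm permutations for the optional permutation p (0 = skip).
#' @param seed integer seed for permutations.
#' @return list: `cutpoint`, `groups` (factor low/high, high = score >
#'   cutpoint), `statistic` (maximal |z|), `p` (improved Bonferroni),
#'   `p_perm` (NA unless `n_perm > 0`), `candidates` (data.frame of
#'   cutpoint and statistic).
#' @export
maxstat_cutpoint <- function(score, times, events,
                             quantile_window = c(0.1, 0.9),
                             n_perm = 0, seed = NULL) {
  if (length(unique(score)) < 2) stop_invalid("all scores identical: no cutpoint exists")
  if (sum(events) < 5) stop_invalid("need >= 5 events")
  qs <- stats::quantile(score, quantile_window, names = FALSE)
  cands <- sort(unique(score[score >= qs[1] & score <= qs[2]]))
  cands <- cands[cands < max(score)]  # a cutpoint at the max leaves 'high' empty
  if (length(cands) == 0) stop_invalid("no candidate cutpoint inside the quantile window")
  if (sum(score >= qs[1] & score <= qs[2]) < 10)
    stop_invalid("fewer than 10 samples inside the quantile window")

  scan <- function(sc) logrank_z_scan(times, events,
                                      outer(sc, cands, ">") + 0)
  zs <- scan(score)
  ok <- is.finite(zs)
  if (!any(ok)) stop_invalid("log-rank statistic undefined at every candidate")
  best <- which(abs(zs) == max(abs(zs[ok])) & ok)[1]  # first = lowest cutpoint
  b <- abs(zs[best])

  q1 <- quantile_window[1]; q2 <- quantile_window[2]
  p <- if (b <= 1) 1 else
    min(1, 4 * stats::dnorm(b) / b +
           stats::dnorm(b) * (b - 1 / b) * log((q2 * (1 - q1)) / (q1 * (1 - q2))))

  p_perm <- NA_real_
  if (n_perm > 0) {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        zi <- scan(sample(score))
        max(abs(zi), na.rm = TRUE) >= b
      }, logical(1)))
    })
    p_perm <- (exceed + 1) / (n_perm + 1)
  }
  groups <- factor(ifelse(score > cands[best], "high", "low"),
                   levels = c("low", "high"))
  list(cutpoint = cands[best], groups = groups, statistic = b, p = p,
       p_perm = p_perm,
       candidates = data.frame(cutpoint = cands, statistic = zs))
}
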