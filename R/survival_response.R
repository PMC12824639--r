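#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator per group via [survival::survfit()], with
#' Greenwood standard errors. When at least two groups are supplied the
#' log-rank test is attached.
#'
#' @param times survival times (> 0, months).
#' @param events 0/1 event indicators.
#' @param groups optional group label per subject (>= 2 subjects per group).
#' @return list of class `tme_survfit`: `table` (data.frame with group,
#'   time, n_risk, n_event, surv, std_err), `logrank` (NULL or
#'   [logrank_test()] output), and `fit` (the underlying survfit object).
#' @export
km_fit <- function(times, events, groups = NULL) {
  if (any(times < 0)) stop_invalid("negative survival times")
  if (!all(events %in% c(0, 1))) stop_invalid("events must be 0/1")
  if (is.null(groups)) {
    fit <- survival::survfit(survival::Surv(times, events) ~ 1)
    tab <- data.frame(group = "all", time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      std_err = fit$std.err * fit$surv)
    lr <- NULL
  } else {
    groups <- factor(groups)
    if (any(table(groups) < 2)) stop_invalid("every group needs >= 2 subjects")
    fit <- survival::survfit(survival::Surv(times, events) ~ groups)
    gid <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
    tab <- data.frame(group = gid, time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      std_err = fit$std.err * fit$surv)
    lr <- if (sum(events) >= 1) logrank_test(times, events, groups) else NULL
  }
  structure(list(table = tab, logrank = lr, fit = fit), class = "tme_survfit")
}

#' Log-rank test between survival groups
#'
#' Observed-minus-expected events over the shared event times with
#' hypergeometric variance (via [survival::survdiff()]); p from a
#' chi-square distribution with `groups - 1` degrees of freedom.
#'
#' @param times,events survival data; at least one event.
#' @param groups group label per subject; >= 2 non-empty groups, and no
#'   declared-but-empty factor levels.
#' @return list: statistic, df, p.
#' @export
logrank_test <- function(times, events, groups) {
  if (!is.factor(groups)) groups <- factor(groups)
  if (any(table(groups) == 0))
    stop_invalid("empty group level(s): ",
                 paste(names(table(groups))[table(groups) == 0], collapse = ", "),
                 "; drop unused levels before testing")
  if (nlevels(groups) < 2) stop_invalid("need >= 2 groups")
  if (sum(events) < 1) stop_invalid("need >= 1 event")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  list(statistic = sd_$chisq, df = df,
       p = stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling, Newton-Raphson to a
#' relative tolerance of 1e-9 within 100 iterations (via
#' [survival::coxph()]). Returns per-covariate hazard ratios with Wald
#' confidence intervals and p-values.
#'
#' @param x numeric vector, matrix or data.frame of covariates (samples in
#'   rows); constant covariates are refused.
#' @param times,events survival data; at least 10 events.
#' @return data.frame: covariate, beta, se, hr, hr_lo, hr_hi, wald_p, with
#'   attributes `"loglik"` (null and fitted) and `"fit"` (the coxph object).
#' @export
cox_fit <- function(x, times, events) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (sum(events) < 10) stop_invalid("need >= 10 events")
  if (any(apply(x, 2, stats::sd) == 0)) stop_invalid("constant covariate(s)")
  fit <- survival::coxph(survival::Surv(times, events) ~ x, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9, iter.max = 100))
  if (any(!is.finite(stats::coef(fit))) || any(!is.finite(sqrt(diag(fit$var)))))
    stop_invalid("Cox fit failed to converge; coefficients or variances ",
                 "non-finite (possible separation)")
  if (any(abs(stats::coef(fit)) > 15))
    warning("very large |beta|: possible separation of the risk sets")
  s <- summary(fit)$coefficients
  out <- data.frame(covariate = colnames(x), beta = s[, "coef"],
                    se = s[, "se(coef)"], hr = exp(s[, "coef"]),
                    hr_lo = exp(s[, "coef"] - 1.959964 * s[, "se(coef)"]),
                    hr_hi = exp(s[, "coef"] + 1.959964 * s[, "se(coef)"]),
                    wald_p = s[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "loglik") <- fit$loglik
  attr(out, "fit") <- fit
  out
}

#' Area under the ROC curve with DeLong-style confidence interval
#'
#' AUC as the Mann-Whitney concordance probability, ties credited 0.5;
#' variance from the DeLong placement decomposition.
#'
#' @param score numeric predictor.
#' @param outcome binary outcome (0/1, logical, or 2-level factor; the
#'   higher/second level is the positive class).
#' @return list: auc, se, ci (95% Wald, clipped to [0, 1]).
#' @export
roc_auc <- function(score, outcome) {
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L else as.integer(outcome)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    stop_invalid("outcome must contain both classes")
  pos <- score[y == 1]; neg <- score[y == 0]
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements
  v10 <- vapply(pos, function(xi) mean((xi > neg) + 0.5 * (xi == neg)), 1.0)
  v01 <- vapply(neg, function(yj) mean((pos > yj) + 0.5 * (pos == yj)), 1.0)
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  list(auc = auc, se = se,
       ci = c(max(0, auc - 1.959964 * se), min(1, auc + 1.959964 * se)))
}

#' Combine TMB and TMEscore for response prediction
#'
#' Fits nested logistic models of a binary response (CR/PR vs SD/PD) on
#' TMB alone, TMEscore alone, and both; the combined score is the two-
#' covariate model's linear predictor. Reports the three AUCs and the
#' likelihood-ratio tests of the combined model against each single-
#' covariate model. Quasi-separation in any fit triggers a warning (the
#' maximum-likelihood fit is still reported).
#'
#' @param tmb,tmescore numeric predictors.
#' @param outcome binary responder indicator (1 = CR/PR), or a character
#'   vector of CR/PR/SD/PD labels (dichotomized internally).
#' @return list: auc_tmb, auc_score, auc_combined, lr_p_vs_tmb,
#'   lr_p_vs_score, loglik (named: tmb, score, combined), n (complete cases).
#' @export
combine_tmb_score <- function(tmb, tmescore, outcome) {
  if (is.character(outcome) || is.factor(outcome)) {
    oc <- as.character(outcome)
    if (!all(oc %in% c("CR", "PR", "SD", "PD", NA)))
      stop_invalid("response labels must be CR/PR/SD/PD")
    outcome <- ifelse(oc %in% c("CR", "PR"), 1L,
                      ifelse(oc %in% c("SD", "PD"), 0L, NA_integer_))
  }
  keep <- stats::complete.cases(tmb, tmescore, outcome)
  d <- data.frame(y = outcome[keep], tmb = tmb[keep], score = tmescore[keep])
  if (nrow(d) < 20) stop_invalid("need >= 20 complete cases")
  if (length(unique(d$y)) < 2) stop_invalid("outcome must contain both classes")
  sep_warn <- FALSE
  fit_glm <- function(f) withCallingHandlers(
    stats::glm(f, data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  m_tmb <- fit_glm(y ~ tmb)
  m_score <- fit_glm(y ~ score)
  m_both <- fit_glm(y ~ tmb + score)
  if (sep_warn)
    warning("quasi-separation detected in a logistic fit; ",
            "AUCs and LR tests use the maximum-likelihood fit")
  ll <- c(tmb = as.numeric(stats::logLik(m_tmb)),
          score = as.numeric(stats::logLik(m_score)),
          combined = as.numeric(stats::logLik(m_both)))
  list(auc_tmb = roc_auc(d$tmb, d$y)$auc,
       auc_score = roc_auc(d$score, d$y)$auc,
       auc_combined = roc_auc(stats::predict(m_both), d$y)$auc,
       lr_p_vs_tmb = stats::pchisq(2 * (ll["combined"] - ll["tmb"]), 1,
                                   lower.tail = FALSE),
       lr_p_vs_score = stats::pchisq(2 * (ll["combined"] - ll["score"]), 1,
                                     lower.tail = FALSE),
       loglik = ll, n = nrow(d))
}

#' Cell-type correlation and prognostic network
#'
#' Pairwise Spearman correlations among estimated cell-type fractions, and
#' a univariate Cox model of survival on each fraction; a cell type is
#' flagged favorable when its hazard ratio is below 1. Constant fraction
#' columns have undefined correlations and are reported as missing.
#'
#' @param fractions data.frame from [estimate_fractions()] (or any table
#'   with `sample_id` and one numeric column per cell type).
#' @param clinical clinical data.frame with sample_id, os_months, os_event.
#' @return list: `nodes` (cell_type, beta, hr, p, neg_log10_p, favorable),
#'   `edges` (type_a, type_b, rho, p), `rho` (correlation matrix).
#' @export
cell_prognostic_network <- function(fractions, clinical) {
  cells <- setdiff(colnames(fractions),
                   c("sample_id", "fit_correlation", "fit_rmse", "perm_pvalue"))
  shared <- intersect(fractions$sample_id, clinical$sample_id)
  if (length(shared) < 10) stop_invalid("need >= 10 shared samples")
  fr <- fractions[match(shared, fractions$sample_id), cells, drop = FALSE]
  cl <- clinical[match(shared, clinical$sample_id), ]

  rho <- matrix(NA_real_, length(cells), length(cells), dimnames = list(cells, cells))
  edges <- list()
  for (i in seq_along(cells)) for (j in seq_along(cells)) if (i < j) {
    xi <- fr[[cells[i]]]; xj <- fr[[cells[j]]]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      edges[[length(edges) + 1]] <- data.frame(type_a = cells[i], type_b = cells[j],
                                               rho = NA_real_, p = NA_real_)
      next
    }
    ct <- suppressWarnings(stats::cor.test(xi, xj, method = "spearman"))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    edges[[length(edges) + 1]] <- data.frame(type_a = cells[i], type_b = cells[j],
                                             rho = unname(ct$estimate), p = ct$p.value)
  }
  diag(rho) <- 1
  nodes <- lapply(cells, function(ct) {
    x <- fr[[ct]]
    if (stats::sd(x) == 0)
      return(data.frame(cell_type = ct, beta = NA, hr = NA, p = NA,
                        neg_log10_p = NA, favorable = NA))
    cx <- cox_fit(x, cl$os_months, cl$os_event)
    data.frame(cell_type = ct, beta = cx$beta, hr = cx$hr, p = cx$wald_p,
               neg_log10_p = -log10(cx$wald_p), favorable = cx$hr < 1)
  })
  list(nodes = do.call(rbind, nodes), edges = do.call(rbind, edges), rho = rho)
}

#' Single-gene association report
#'
#' For one gene: Wilcoxon rank-sum tests of its expression across each
#' binary clinical contrast (ER/PR/HER2 status where both levels are
#' present), Spearman correlation with every estimated cell-type fraction,
#' and a median-split Kaplan-Meier / log-rank survival analysis. All
#' p-values are BH-adjusted within the report.
#'
#' @param m expression matrix (genes x samples).
#' @param gene_id gene to report on; a missing gene raises an error listing
#'   the nearest ids.
#' @param fractions data.frame from [estimate_fractions()], or NULL.
#' @param clinical clinical data.frame.
#' @return list: `clinical_tests` (contrast, statistic, p, q),
#'   `fraction_correlations` (cell_type, rho, p, q), `survival` (list:
#'   logrank, km, p, q), `gene_id`.
#' @export
gene_report <- function(m, gene_id, fractions = NULL, clinical) {
  if (!gene_id %in% rownames(m)) {
    near <- utils::head(agrep(gene_id, rownames(m), max.distance = 0.3,
                              value = TRUE), 5)
    stop_invalid("gene '", gene_id, "' not found",
                 if (length(near)) paste0("; nearest: ", paste(near, collapse = ", ")))
  }
  shared <- intersect(colnames(m), clinical$sample_id)
  expr <- m[gene_id, shared]
  cl <- clinical[match(shared, clinical$sample_id), ]
  ps <- numeric(0)

  rows <- list()
  for (col in intersect(c("er", "pr", "her2"), colnames(cl))) {
    v <- cl[[col]]
    if (length(unique(stats::na.omit(v))) < 2) next
    wt <- stats::wilcox.test(expr[v == "pos"], expr[v == "neg"])
    rows[[col]] <- data.frame(contrast = paste0(col, " pos vs neg"),
                              statistic = unname(wt$statistic), p = wt$p.value)
  }
  clin <- do.call(rbind, rows)
  if (!is.null(clin)) ps <- c(ps, clin$p)

  frc <- NULL
  if (!is.null(fractions)) {
    cells <- setdiff(colnames(fractions),
                     c("sample_id", "fit_correlation", "fit_rmse", "perm_pvalue"))
    fr <- fractions[match(shared, fractions$sample_id), , drop = FALSE]
    frc <- do.call(rbind, lapply(cells, function(ct) {
      x <- fr[[ct]]
      if (stats::sd(x) == 0) return(data.frame(cell_type = ct, rho = NA, p = NA))
      s <- suppressWarnings(stats::cor.test(expr, x, method = "spearman"))
      data.frame(cell_type = ct, rho = unname(s$estimate), p = s$p.value)
    }))
    ps <- c(ps, stats::na.omit(frc$p))
  }

  surv <- NULL
  if (all(c("os_months", "os_event") %in% colnames(cl))) {
    split_ <- factor(ifelse(expr > stats::median(expr), "high", "low"),
                     levels = c("low", "high"))
    if (nlevels(droplevels(split_)) == 2) {
      lr <- logrank_test(cl$os_months, cl$os_event, split_)
      surv <- list(logrank = lr, km = km_fit(cl$os_months, cl$os_event, split_),
                   p = lr$p)
      ps <- c(ps, lr$p)
    }
  }

  qs <- stats::p.adjust(ps, method = "BH")
  qi <- 0
  take_q <- function(p) { if (is.na(p)) return(NA_real_); qi <<- qi + 1; qs[qi] }
  if (!is.null(clin)) clin$q <- vapply(clin$p, take_q, 1.0)
  if (!is.null(frc)) frc$q <- vapply(frc$p, take_q, 1.0)
  if (!is.null(surv)) surv$q <- take_q(surv$p)
  list(gene_id = gene_id, clinical_tests = clin,
       fraction_correlations = frc, survival = surv)
}
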