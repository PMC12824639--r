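test_that("KM estimator equals the empirical survival function without censoring", {
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$surv, c(2 / 3, 1 / 3, 0))

  km_c <- km_fit(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km_c$table$surv == 1))
  expect_error(km_fit(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM matches a hand-computed product over risk sets with mixed censoring", {
  times <- c(1, 2, 2, 3, 4, 5)
  events <- c(1, 1, 0, 1, 0, 1)
  # risk sets: t=1 n=6 d=1; t=2 n=5 d=1; t=3 n=3 d=1; t=5 n=1 d=1
  oracle <- cumprod(c(1 - 1 / 6, 1 - 1 / 5, 1 - 1 / 3, 1 - 1 / 1))
  km <- km_fit(times, events)
  expect_equal(km$table$surv[km$table$n_event > 0], oracle, tolerance = 1e-12)
})

test_that("log-rank is null on duplicated groups and matches its permutation reference", {
  times <- c(3, 5, 7, 9, 11); events <- c(1, 0, 1, 1, 0)
  lr0 <- logrank_test(c(times, times), c(events, events), rep(c("a", "b"), each = 5))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  set.seed(1)
  tt <- rexp(20, 0.1); ee <- rbinom(20, 1, 0.8); gg <- rep(c("a", "b"), 10)
  lr <- logrank_test(tt, ee, gg)
  perm_stats <- replicate(4000, {
    survival::survdiff(survival::Surv(tt, ee) ~ sample(gg))$chisq
  })
  p_perm <- mean(perm_stats >= lr$statistic)
  expect_lt(abs(p_perm - lr$p), 0.05)

  expect_error(logrank_test(tt, ee, rep("a", 20)), "2 groups")
  expect_error(logrank_test(tt, ee, factor(gg, levels = c("a", "b", "c"))),
               "empty group")
})

test_that("log-rank is invariant under monotone time transformations", {
  set.seed(2)
  tt <- rexp(60, 0.1); ee <- rbinom(60, 1, 0.7); gg <- rep(c("a", "b"), 30)
  lr1 <- logrank_test(tt, ee, gg)
  lr2 <- logrank_test(tt^3, ee, gg)
  lr3 <- logrank_test(log(tt + 1), ee, gg)
  expect_equal(lr1$statistic, lr2$statistic, tolerance = 1e-9)
  expect_equal(lr1$statistic, lr3$statistic, tolerance = 1e-9)
})

test_that("Cox regression recovers a known hazard ratio and is scale-equivariant", {
  set.seed(3)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  sv <- sim_survival(n, log(2) * x, base_hazard = 0.05, censor_rate = 0.021,
                     seed = 3)
  fit <- cox_fit(x, sv$times, sv$events)
  expect_gt(fit$hr, 1.7); expect_lt(fit$hr, 2.35)

  fit2 <- cox_fit(2 * x, sv$times, sv$events)
  expect_equal(fit2$beta, fit$beta / 2, tolerance = 1e-9)

  expect_error(cox_fit(rep(1, n), sv$times, sv$events), "constant")
  expect_error(cox_fit(x[1:20], sv$times[1:20], rep(0, 20)), "events")
})

test_that("null covariates stay within two standard errors most of the time", {
  inside <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 150
    x <- rnorm(n)
    sv <- sim_survival(n, rep(0, n), seed = 2000 + s)
    fit <- cox_fit(x, sv$times, sv$events)
    abs(fit$beta) < 2 * fit$se
  }, logical(1))
  expect_gte(sum(inside), 90)
})

test_that("AUC equals brute-force pair counting, with exact edge cases", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3))$auc, 1.0)
  expect_equal(roc_auc(rep(5, 10), rep(0:1, each = 5))$auc, 0.5)

  set.seed(4)
  for (i in 1:20) {
    score <- sample(1:6, 12, replace = TRUE)  # ties on purpose
    y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) next
    pos <- score[y == 1]; neg <- score[y == 0]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(score, y)$auc, brute, tolerance = 1e-12)
    expect_equal(roc_auc(score, y)$auc + roc_auc(-score, y)$auc, 1)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC and DeLong variance agree with pROC", {
  set.seed(5)
  score <- rnorm(60); y <- rbinom(60, 1, 0.5)
  ours <- roc_auc(score, y)
  ref <- pROC::roc(y, score, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(ours$se, sqrt(pROC::var(ref)), tolerance = 1e-6)
})

test_that("combining TMB and TMEscore improves prediction when both inform", {
  set.seed(6)
  n <- 400
  tmb <- rnorm(n); score <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * tmb + 0.8 * score))
  res <- combine_tmb_score(tmb, score, y)
  expect_gt(res$auc_combined, max(res$auc_tmb, res$auc_score))
  expect_gte(res$loglik["combined"], res$loglik["tmb"])
  expect_gte(res$loglik["combined"], res$loglik["score"])
  expect_lt(res$lr_p_vs_tmb, 0.05)

  # response-label interface
  resp <- ifelse(y == 1, sample(c("CR", "PR"), n, TRUE), sample(c("SD", "PD"), n, TRUE))
  res2 <- combine_tmb_score(tmb, score, resp)
  expect_equal(res2$auc_combined, res$auc_combined)
  expect_error(combine_tmb_score(tmb[1:10], score[1:10], y[1:10]), "20 complete")
})

test_that("the LR test is null-calibrated when the second covariate is noise", {
  set.seed(7)
  ps <- vapply(1:100, function(s) {
    n <- 150
    tmb <- rnorm(n)
    y <- rbinom(n, 1, plogis(tmb))
    combine_tmb_score(tmb, rnorm(n), y)$lr_p_vs_tmb
  }, 1.0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the cell network reports correlations, compositional limits and risk flags", {
  set.seed(8)
  n <- 500
  fr <- t(vapply(seq_len(n), function(i) {
    v <- rgamma(3, c(2, 2, 2)); v / sum(v)
  }, numeric(3)))
  colnames(fr) <- c("ctA", "ctB", "ctC")
  # hazard doubles per +0.1 of ctA
  sv <- sim_survival(n, log(2) / 0.1 * (fr[, 1] - mean(fr[, 1])), seed = 8)
  fractions <- data.frame(sample_id = sprintf("s%03d", 1:n), fr)
  clinical <- data.frame(sample_id = fractions$sample_id,
                         os_months = sv$times, os_event = sv$events)
  net <- cell_prognostic_network(fractions, clinical)
  a <- net$nodes[net$nodes$cell_type == "ctA", ]
  expect_false(a$favorable)
  expect_lt(a$p, 0.01)
  # fractions on a simplex cannot all correlate positively
  expect_lt(min(net$edges$rho), 0)

  # duplicated cell type gives rho exactly 1
  fr2 <- cbind(fractions, ctA2 = fractions$ctA)
  net2 <- cell_prognostic_network(fr2, clinical)
  e <- net2$edges
  expect_equal(e$rho[e$type_a == "ctA" & e$type_b == "ctA2"], 1)
})

test_that("the gene report ties together clinical contrasts, fractions and survival", {
  set.seed(9)
  n <- 120
  samples <- sprintf("s%03d", 1:n)
  fr <- t(vapply(seq_len(n), function(i) { v <- rgamma(3, 2); v / sum(v) },
                 numeric(3)))
  colnames(fr) <- c("ctA", "ctB", "ctC")
  g_target <- 10 * fr[, "ctB"] + rnorm(n, 0, 0.1)  # monotone in ctB
  m <- rbind(GENE1 = g_target, GENE2 = rnorm(n, 5))
  colnames(m) <- samples
  sv <- sim_survival(n, rep(0, n), seed = 9)
  clinical <- data.frame(sample_id = samples, os_months = sv$times,
                         os_event = sv$events,
                         er = sample(c("pos", "neg"), n, TRUE),
                         pr = sample(c("pos", "neg"), n, TRUE))
  fractions <- data.frame(sample_id = samples, fr)
  rep_ <- gene_report(m, "GENE1", fractions, clinical)
  fc <- rep_$fraction_correlations
  expect_equal(fc$cell_type[which.max(abs(fc$rho))], "ctB")
  expect_true(all(rep_$clinical_tests$q >= rep_$clinical_tests$p))

  # identical expression in both ER groups: Wilcoxon p = 1
  m2 <- m
  m2["GENE2", ] <- rep(seq_len(4), length.out = n)
  clinical2 <- clinical
  clinical2$er <- rep(c("pos", "neg"), n / 2)
  m2["GENE2", clinical2$er == "neg"] <- m2["GENE2", clinical2$er == "pos"]
  rep2 <- suppressWarnings(gene_report(m2, "GENE2", NULL, clinical2))
  expect_equal(rep2$clinical_tests$p[rep2$clinical_tests$contrast == "er pos vs neg"], 1)

  expect_error(gene_report(m, "GEN1", fractions, clinical), "nearest")
})

test_that("a strong median-split expression effect is detected almost always", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 400
    expr <- rnorm(n)
    high <- expr > median(expr)
    sv <- sim_survival(n, log(2.5) * high, seed = 3000 + s)
    logrank_test(sv$times, sv$events, high)$p < 0.001
  }, logical(1))
  expect_gte(sum(hits), 95)
})
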