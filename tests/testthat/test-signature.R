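mk_expr <- function(n_genes, n_samples, seed = 1, mean = 5, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n_samples)))
  m
}

test_that("a gene identical across groups shows no effect and p near 1", {
  m <- mk_expr(20, 12, seed = 1)
  labels <- rep(c("A", "B"), each = 6)
  m["g001", labels == "B"] <- m["g001", labels == "A"]
  deg <- differential_genes(m, labels, contrast = "pairwise")
  row <- deg[deg$gene_id == "g001", ]
  expect_equal(row$effect, 0)
  expect_gt(row$p, 0.999)
})

test_that("a planted two-unit shift is the top discovery", {
  m <- mk_expr(500, 60, seed = 2, sd = 0.5)
  labels <- rep(c("A", "B"), each = 30)
  m["g007", labels == "A"] <- m["g007", labels == "A"] + 2.0
  deg <- differential_genes(m, labels, contrast = "pairwise")
  expect_equal(deg$gene_id[which.min(deg$q)], "g007")
  expect_lt(deg$q[deg$gene_id == "g007"], 0.05)
  expect_true(all(deg$q >= deg$p))
  expect_true(all(deg$q >= 0 & deg$q <= 1))
})

test_that("differential results are invariant to sample order and label encoding", {
  m <- mk_expr(50, 24, seed = 3)
  labels <- rep(c("A", "B"), each = 12)
  a <- differential_genes(m, labels, contrast = "pairwise")
  perm <- sample(24)
  b <- differential_genes(m[, perm], labels[perm], contrast = "pairwise")
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  # relabelled groups flip the contrast direction but not the inference
  c_ <- differential_genes(m, ifelse(labels == "A", "zzz", "aaa"),
                           contrast = "pairwise")
  expect_equal(abs(a$statistic), abs(c_$statistic), tolerance = 1e-12)
  expect_equal(a$p, c_$p, tolerance = 1e-12)
})

test_that("group size and contrast contracts are enforced", {
  m <- mk_expr(10, 8, seed = 4)
  expect_error(differential_genes(m, c(rep("A", 6), "B", "B")), ">= 3 samples")
  deg1 <- differential_genes(m, rep(c("A", "B"), each = 4), contrast = "pairwise")
  expect_error(consistent_genes(deg1), ">= 2 contrasts")
})

test_that("consistent genes form the cross-contrast intersection", {
  fake <- function(contrast, sig_genes, all_genes) {
    data.frame(gene_id = all_genes, contrast = contrast, effect = 0,
               statistic = 0, p = 1,
               q = ifelse(all_genes %in% sig_genes, 0.01, 0.5),
               significant = all_genes %in% sig_genes)
  }
  genes <- c("A", "B", "C", "D", "E")
  deg <- rbind(fake("c1", c("A", "B", "C"), genes),
               fake("c2", c("B", "C", "D"), genes))
  expect_equal(consistent_genes(deg), c("B", "C"))
  expect_equal(signature_pool(deg), c("A", "B", "C", "D"))

  deg_none <- rbind(fake("c1", c("A", "B"), genes), fake("c2", character(0), genes))
  expect_message(res <- consistent_genes(deg_none), "no gene")
  expect_length(res, 0)

  deg_same <- rbind(fake("c1", c("A", "C"), genes), fake("c2", c("A", "C"), genes))
  expect_equal(consistent_genes(deg_same), c("A", "C"))
})

test_that("gene K-means recovers anti-correlated blocks and keeps duplicates together", {
  set.seed(5)
  base <- rnorm(30)
  block1 <- t(replicate(10, base + rnorm(30, 0, 0.1)))
  block2 <- t(replicate(10, -base + rnorm(30, 0, 0.1)))
  m <- rbind(block1, block2)
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:30))
  mz <- zscore_genes(m)
  ms <- cluster_genes(mz, k = 2, seed = 5)
  lab <- rep(NA_integer_, 20)
  names(lab) <- rownames(m)
  for (i in seq_along(ms$modules)) lab[ms$modules[[i]]] <- i
  expect_equal(ari(lab, rep(1:2, each = 10)), 1)

  # duplicated rows always co-cluster
  m2 <- m; m2["g20", ] <- m2["g01", ]
  ms2 <- cluster_genes(zscore_genes(m2), k = 2, seed = 5)
  in_same <- any(vapply(ms2$modules, function(g) all(c("g01", "g20") %in% g),
                        logical(1)))
  expect_true(in_same)
  expect_error(cluster_genes(mz[1:1, , drop = FALSE], k = 2), "fewer genes")
})

test_that("planted cohort modules are recovered by gene clustering", {
  sig <- make_signature_matrix(4, 5, seed = 6)
  cfg <- simulation_config(n_samples = 150, n_cell_types = 4,
                           n_markers_per_type = 5,
                           archetypes = make_archetypes(4, 2),
                           group_weights = c(0.5, 0.5),
                           module_spec = list(list(size = 25, beta = 0.5),
                                              list(size = 25, beta = -0.5)),
                           n_noise_genes = 0, seed = 6)
  co <- simulate_cohort(cfg, sig)
  genes <- unlist(co$truth$true_module_genes)
  mz <- zscore_genes(linear_to_log2(co$expr[genes, ]))
  ms <- cluster_genes(mz, k = 2, seed = 6)
  lab <- rep(NA_integer_, length(genes)); names(lab) <- genes
  for (i in seq_along(ms$modules)) lab[ms$modules[[i]]] <- i
  truth <- rep(1:2, each = 25)
  expect_gte(ari(lab, truth), 0.9)
})

test_that("forest pruning keeps the arithmetic contract and is monotone", {
  m <- mk_expr(20, 40, seed = 7)
  labels <- rep(c("A", "B"), each = 20)
  m[1:5, labels == "A"] <- m[1:5, labels == "A"] + 2
  ms <- structure(list(modules = list(module_1 = rownames(m)[1:10],
                                      module_2 = rownames(m)[11:20]),
                       betas = NULL, signs = NULL),
                  class = "gene_module_set")
  full <- reduce_by_forest(m, ms, labels, keep_fraction = 1.0, seed = 7)
  expect_identical(lapply(full$modules, sort), lapply(ms$modules, sort))

  half <- reduce_by_forest(m, ms, labels, keep_fraction = 0.5, seed = 7)
  expect_length(half$modules$module_1, 5)
  expect_length(half$modules$module_2, 5)

  eighty <- reduce_by_forest(m, ms, labels, keep_fraction = 0.8, seed = 7)
  expect_true(all(half$modules$module_1 %in% eighty$modules$module_1))
  expect_true(all(half$modules$module_2 %in% eighty$modules$module_2))

  expect_error(reduce_by_forest(m, ms, rep("A", 40)), "2 classes")
  expect_error(reduce_by_forest(m, ms, labels, keep_fraction = 0), "keep_fraction")
})

test_that("informative genes outrank independent noise in importance", {
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    labels <- rep(c("A", "B"), each = n / 2)
    info <- matrix(rnorm(5 * n), 5, n) +
      2 * matrix(rep(as.numeric(labels == "A"), each = 5), 5, n)
    noise <- matrix(rnorm(5 * n), 5, n)
    m <- rbind(info, noise)
    dimnames(m) <- list(c(paste0("info", 1:5), paste0("noise", 1:5)),
                        paste0("s", seq_len(n)))
    ms <- structure(list(modules = list(module_1 = rownames(m)), betas = NULL,
                         signs = NULL), class = "gene_module_set")
    pr <- reduce_by_forest(m, ms, labels, keep_fraction = 1.0, seed = s)
    imp <- attr(pr, "importance")
    min(imp[paste0("info", 1:5)]) > max(imp[paste0("noise", 1:5)])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
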