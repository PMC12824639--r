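# Shared fixture builders; everything is generated in code under fixed seeds.

# Two well-separated Gaussian point clouds (samples x features).
separable_clouds <- function(n_per = 20, d = 4, gap = 50, seed = 1) {
  withr_seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = gap), n_per, d))
  rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  list(x = x, truth = rep(1:2, each = n_per))
}

# Cell-fraction profiles from G Dirichlet archetypes (samples x types);
# the default panel width matches the LM22-like generator default.
archetype_fractions <- function(n = 60, n_types = 22, n_groups = 3,
                                high = 8, low = 1, seed = 1) {
  withr_seed(seed)
  arch <- make_archetypes(n_types, n_groups, high = high, low = low)
  g <- rep_len(seq_len(n_groups), n)
  x <- t(vapply(g, function(gg) {
    a <- arch[[gg]]
    v <- rgamma(n_types, shape = a)
    v / sum(v)
  }, numeric(n_types)))
  rownames(x) <- sprintf("S%03d", seq_len(n))
  colnames(x) <- sprintf("CT%02d", seq_len(n_types))
  list(x = x, truth = g)
}

# Exponential survival with a binary or continuous covariate effect.
sim_survival <- function(n, lp, base_hazard = 0.05, censor_rate = 0.02,
                         seed = 1) {
  withr_seed(seed)
  tt <- rexp(n, rate = base_hazard * exp(lp))
  cc <- rexp(n, rate = censor_rate)
  list(times = pmin(tt, cc), events = as.integer(tt <= cc))
}

# set.seed without leaking the helper's name into test output
withr_seed <- function(seed) set.seed(seed)

# Adjusted Rand index oracle (mclust); agreement maximized over label
# permutations by construction of the index.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Brute-force Benjamini-Hochberg step-up: q_i = min over j >= rank(i) of
# p_(j) * m / j, computed literally from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)  # rank of p[i]
    q[i] <- min(1, min(sort(p)[r:m] * m / (r:m)))
  }
  q
}

# Direct running-sum GSEA oracle for a 0/1 hit vector over a ranking.
es_oracle <- function(scores_sorted, hit, p = 1) {
  N <- length(hit); K <- sum(hit)
  inc <- abs(scores_sorted)^p * hit
  inc <- if (sum(inc) == 0) hit / K else inc / sum(inc)
  run <- cumsum(inc - (1 - hit) / (N - K))
  unname(run[which.max(abs(run))])
}
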