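#' Dirichlet archetypes for latent TME groups
#'
#' One concentration vector per group: each group concentrates mass on its
#' own block of cell types (`high`) and spreads the rest (`low`). With the
#' default 8-vs-1 contrast the groups are well separated on the fraction
#' simplex, the regime in which clustering is expected to recover them.
#'
#' @param n_cell_types number of cell types.
#' @param n_groups number of latent groups (default 3).
#' @param high,low concentration inside/outside the group's block.
#' @return list of `n_groups` numeric vectors of length `n_cell_types`.
#' @export
make_archetypes <- function(n_cell_types, n_groups = 3, high = 8, low = 1) {
  stopifnot(n_cell_types >= n_groups, n_groups >= 1)
  blocks <- split(seq_len(n_cell_types),
                  rep_len(seq_len(n_groups), n_cell_types))
  lapply(seq_len(n_groups), function(g) {
    a <- rep(low, n_cell_types)
    a[blocks[[g]]] <- high
    a
  })
}

#' Simulation configuration for a synthetic TME cohort
#'
#' Collects and validates all generator parameters. Defaults describe a
#' mid-sized expression cohort: three well-separated TME groups, moderate
#' multiplicative noise on marker genes, two batches, and two planted
#' prognostic modules of opposite effect (one hazardous, one protective)
#' with exponential survival on a monthly time scale.
#'
#' @param n_samples cohort size.
#' @param n_cell_types,n_markers_per_type signature dimensions; must match
#'   the signature matrix passed to [simulate_cohort()]. Defaults emulate
#'   the granularity of the LM22 immune reference (22 cell types, about 25
#'   markers each); tests and examples often use smaller panels for speed.
#' @param archetypes list of Dirichlet concentration vectors, one per latent
#'   group (default [make_archetypes()] with 3 groups).
#' @param group_weights group membership probabilities, summing to 1.
#' @param noise_sd log-scale SD of multiplicative lognormal noise applied to
#'   marker-gene expression (linear scale stays non-negative).
#' @param n_batches,batch_shift_sd number of batches and SD of the additive
#'   per-batch, per-gene shift applied on the log2 scale.
#' @param module_spec list of `list(size =, beta =)` entries: number of genes
#'   and per-unit log-hazard of each planted prognostic module (beta applies
#'   to the module's mean z-scored expression).
#' @param module_activity_sd SD of the per-sample latent activity shared by
#'   all genes of a module; this is what makes a module a co-expression
#'   unit rather than a loose set of group-shifted genes.
#' @param n_noise_genes unstructured filler genes with no group or survival
#'   signal.
#' @param baseline_hazard,censor_rate exponential event and censoring rates
#'   per month; both independent given the covariates.
#' @param tmb_link slope linking the latent score (negative Cox linear
#'   predictor) to tumor mutational burden in mutations/Mb.
#' @param seed integer master seed; all sampling derives from it.
#' @return object of class `tme_sim_config`.
#' @export
simulation_config <- function(n_samples = 300,
                              n_cell_types = 22,
                              n_markers_per_type = 25,
                              archetypes = make_archetypes(n_cell_types, 3),
                              group_weights = rep(1 / length(archetypes), length(archetypes)),
                              noise_sd = 0.1,
                              n_batches = 2,
                              batch_shift_sd = 0.5,
                              module_spec = list(list(size = 30, beta = 0.8),
                                                 list(size = 30, beta = -0.8)),
                              module_activity_sd = 0.5,
                              n_noise_genes = 100,
                              baseline_hazard = 0.02,
                              censor_rate = 0.01,
                              tmb_link = 4,
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_cell_types = as.integer(n_cell_types),
              n_markers_per_type = as.integer(n_markers_per_type),
              archetypes = archetypes,
              group_weights = as.numeric(group_weights),
              noise_sd = noise_sd, n_batches = as.integer(n_batches),
              batch_shift_sd = batch_shift_sd,
              module_spec = module_spec,
              module_activity_sd = module_activity_sd,
              n_noise_genes = as.integer(n_noise_genes),
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              tmb_link = tmb_link, seed = as.integer(seed))
  if (cfg$n_samples < 1 || cfg$n_cell_types < 1 || cfg$n_markers_per_type < 1)
    stop_invalid("all counts must be >= 1")
  if (abs(sum(cfg$group_weights) - 1) > 1e-12)
    stop_invalid("group_weights must sum to 1")
  if (length(cfg$archetypes) != length(cfg$group_weights))
    stop_invalid("one group weight per archetype required")
  if (any(vapply(cfg$archetypes, length, 1L) != cfg$n_cell_types))
    stop_invalid("each archetype must have n_cell_types concentrations")
  if (cfg$noise_sd < 0 || cfg$batch_shift_sd < 0 || cfg$module_activity_sd < 0)
    stop_invalid("noise_sd, batch_shift_sd and module_activity_sd must be >= 0")
  if (cfg$baseline_hazard <= 0 || cfg$censor_rate <= 0)
    stop_invalid("baseline_hazard and censor_rate must be > 0")
  for (m in cfg$module_spec)
    if (is.null(m$size) || is.null(m$beta) || m$size < 2)
      stop_invalid("each module_spec entry needs size >= 2 and beta")
  class(cfg) <- "tme_sim_config"
  cfg
}

#' Simulate a synthetic TME cohort
#'
#' Generates a gene-by-sample expression matrix (linear TPM-like scale), a
#' clinical table and the ground truth used to test every downstream stage.
#'
#' Per sample: a latent group is drawn with `group_weights`; cell fractions
#' come from that group's Dirichlet archetype; marker-gene expression is the
#' signature-weighted mixture `sig %*% fractions` times lognormal noise
#' `exp(N(0, noise_sd))`. Planted module genes are generated on the log2
#' scale as a gene baseline plus a per-sample module activity (a
#' group-specific mean plus Gaussian latent noise, shared by all genes of
#' the module so the module coheres as a co-expression unit) plus gene-level
#' Gaussian noise, then exponentiated. Batch effects are additive per-batch,
#' per-gene Gaussian shifts applied on the log2 scale (the scale on which
#' empirical-Bayes batch correction operates). Survival times are exponential
#' with hazard `baseline_hazard * exp(sum_m beta_m * zbar_m)` where `zbar_m`
#' is the module's mean z-scored (pre-batch) expression; censoring is an
#' independent exponential with rate `censor_rate`. TMB is
#' `max(0, 10 + tmb_link * latent + N(0, 2))` and 4-level response labels
#' (CR/PR/SD/PD) are drawn from a proportional-odds model monotone in the
#' latent score (the negative Cox linear predictor), with marginal
#' probabilities near 10/25/35/30% CR/PR/SD/PD at latent 0.
#'
#' @param cfg a [simulation_config()] object.
#' @param sig signature matrix from [make_signature_matrix()]; must have
#'   `cfg$n_cell_types` columns and rows covering the marker genes.
#' @return list with elements `expr` (linear-scale matrix, genes x samples),
#'   `clinical` (data.frame: sample_id, os_months, os_event, er, pr, her2,
#'   subtype, batch, tmb, response), and `truth` (list: true_fractions,
#'   true_group, true_module_genes, true_betas, latent_score, linear_predictor).
#' @examples
#' sig <- make_signature_matrix(6, 10, seed = 1)
#' cohort <- simulate_cohort(simulation_config(n_samples = 50, seed = 1), sig)
#' dim(cohort$expr)
#' @export
simulate_cohort <- function(cfg, sig) {
  if (!inherits(cfg, "tme_sim_config")) stop_invalid("cfg must come from simulation_config()")
  if (!is.matrix(sig) || ncol(sig) != cfg$n_cell_types)
    stop_invalid("signature matrix must have cfg$n_cell_types columns")
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    G <- length(cfg$archetypes)
    samples <- sprintf("S%04d", seq_len(n))
    group <- sample.int(G, n, replace = TRUE, prob = cfg$group_weights)

    fractions <- matrix(0, n, cfg$n_cell_types,
                        dimnames = list(samples, colnames(sig)))
    for (g in seq_len(G)) {
      idx <- which(group == g)
      if (length(idx)) fractions[idx, ] <- rdirichlet(length(idx), cfg$archetypes[[g]])
    }

    # marker genes: signature-weighted mixture with multiplicative noise
    marker <- sig %*% t(fractions)
    if (cfg$noise_sd > 0)
      marker <- marker * exp(matrix(stats::rnorm(length(marker), 0, cfg$noise_sd),
                                    nrow(marker), ncol(marker)))

    # planted prognostic modules on the log2 scale: shared group profile per
    # module makes genes cohere within a module and differ across TME groups
    n_mod <- length(cfg$module_spec)
    module_genes <- list(); module_log2 <- NULL
    group_means <- matrix(stats::rnorm(n_mod * G, 0, 1), n_mod, G)
    for (m in seq_len(n_mod)) {
      sz <- as.integer(cfg$module_spec[[m]]$size)
      gid <- sprintf("MOD%d_G%03d", m, seq_len(sz))
      base <- stats::rnorm(sz, 6, 1)
      # shared latent activity makes the module a co-expression unit
      activity <- group_means[m, group] +
        stats::rnorm(n, 0, cfg$module_activity_sd)
      block <- matrix(stats::rnorm(sz * n, 0, 0.5), sz, n) + base +
        matrix(activity, sz, n, byrow = TRUE)
      rownames(block) <- gid
      module_genes[[paste0("module_", m)]] <- gid
      module_log2 <- rbind(module_log2, block)
    }
    noise_log2 <- NULL
    if (cfg$n_noise_genes > 0) {
      noise_log2 <- matrix(stats::rnorm(cfg$n_noise_genes * n, 0, 0.7),
                           cfg$n_noise_genes, n) + stats::rnorm(cfg$n_noise_genes, 5, 1)
      rownames(noise_log2) <- sprintf("NOISE_G%03d", seq_len(cfg$n_noise_genes))
    }

    # survival link uses the clean (pre-batch) module signal
    betas <- vapply(cfg$module_spec, function(m) m$beta, 1.0)
    names(betas) <- names(module_genes)
    lp <- rep(0, n)
    for (m in seq_len(n_mod)) {
      z <- t(scale(t(module_log2[module_genes[[m]], , drop = FALSE])))
      lp <- lp + betas[m] * colMeans(z)
    }
    hazard <- cfg$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n, rate = hazard)
    t_cens <- stats::rexp(n, rate = cfg$censor_rate)
    os_months <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)

    latent <- -lp
    tmb <- pmax(0, 10 + cfg$tmb_link * latent + stats::rnorm(n, 0, 2))
    # proportional odds, ordered worst -> best: PD < SD < PR < CR
    cuts <- stats::qlogis(c(0.30, 0.65, 0.90))
    y <- latent + stats::rlogis(n)
    response <- cut(y, c(-Inf, cuts, Inf), labels = c("PD", "SD", "PR", "CR"))
    response <- as.character(response)

    er <- ifelse(stats::runif(n) < stats::plogis(0.4 + 0.3 * latent), "pos", "neg")
    pr <- ifelse(stats::runif(n) < 0.5, "pos", "neg")
    her2 <- ifelse(stats::runif(n) < 0.3, "pos", "neg")

    batch <- sprintf("batch%d", sample(rep_len(seq_len(cfg$n_batches), n)))

    expr <- rbind(marker,
                  if (!is.null(module_log2)) 2^module_log2,
                  if (!is.null(noise_log2)) 2^noise_log2)
    colnames(expr) <- samples
    if (cfg$n_batches > 1 && cfg$batch_shift_sd > 0) {
      shifts <- matrix(stats::rnorm(nrow(expr) * cfg$n_batches, 0, cfg$batch_shift_sd),
                       nrow(expr), cfg$n_batches,
                       dimnames = list(rownames(expr), sprintf("batch%d", seq_len(cfg$n_batches))))
      expr <- 2^(log2(expr + 1) + shifts[, batch]) - 1
      expr[expr < 0] <- 0
    }

    clinical <- data.frame(sample_id = samples,
                           os_months = os_months, os_event = os_event,
                           er = er, pr = pr, her2 = her2,
                           subtype = paste0("TMEgroup-", LETTERS[group]),
                           batch = batch, tmb = tmb, response = response,
                           stringsAsFactors = FALSE)
    truth <- list(true_fractions = fractions,
                  true_group = stats::setNames(group, samples),
                  true_module_genes = module_genes,
                  true_betas = betas,
                  latent_score = stats::setNames(latent, samples),
                  linear_predictor = stats::setNames(lp, samples))
    list(expr = expr, clinical = clinical, truth = truth)
  })
}
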