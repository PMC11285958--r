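# Seed derivation: every stage draws from the single config seed salted by
# a stage name, so stages are independently reproducible.
salt_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Configuration for a simulated expression cohort
#'
#' Defines the generative model used by [simulate_cohort()]: a latent
#' standard-normal activity per anchor, planted co-expression modules at a
#' target Pearson correlation, latent signature activities tied to the
#' first anchor with a chosen sign and strength, exponential survival with
#' a log-linear hazard, and optional additive group effects
#' (tumor/normal shift, ordinal stage trend, paired pre/post treatment
#' effect).
#'
#' @param n_samples number of samples (>= 10).
#' @param n_background_genes number of pure-noise background genes.
#' @param anchors character vector of anchor gene names.
#' @param module_size module genes per anchor (>= 2); recycled.
#' @param target_rho target Pearson correlation between each module gene
#'   and its anchor's latent activity, in (-1, 1); recycled over anchors.
#' @param signatures data.frame with columns `name`, `size`, `sign`
#'   (+1/-1) and `gamma` (strength >= 0).  Signature activities are
#'   `sign * gamma * a + noise` where `a` is the first anchor's latent
#'   activity.
#' @param noise_sd standard deviation of gene-level noise.
#' @param signature_rho correlation of signature member genes with their
#'   signature's latent activity.
#' @param baseline_hazard exponential baseline hazard rate (> 0).
#' @param coef_anchor log-hazard coefficient on the first anchor's latent
#'   activity.
#' @param coef_signature log-hazard coefficient on the designated
#'   survival-driving signature's activity.
#' @param survival_signature name of the survival-driving signature
#'   (default: first signature, if any).
#' @param censoring_fraction target expected fraction censored, in [0, 1).
#' @param tumor_normal_shift additive shift applied to anchor and module
#'   genes of tumor samples (activates a 50/50 tumor/normal labelling
#'   when non-zero).
#' @param stage_slope additive per-stage slope on anchor and module genes
#'   (activates uniform stage 1-4 labels when non-zero).
#' @param paired_treatment_effect additive shift on anchor and module
#'   genes of "post" samples (activates pre/post pairing when non-zero:
#'   samples are paired consecutively into patients).
#' @param seed integer random seed.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 200,
                              n_background_genes = 500,
                              anchors = "ANCHOR1",
                              module_size = 50,
                              target_rho = 0.5,
                              signatures = NULL,
                              noise_sd = 1,
                              signature_rho = 0.5,
                              baseline_hazard = 0.05,
                              coef_anchor = 0,
                              coef_signature = 0,
                              survival_signature = NULL,
                              censoring_fraction = 0.2,
                              tumor_normal_shift = 0,
                              stage_slope = 0,
                              paired_treatment_effect = 0,
                              seed = 1L) {
  if (n_samples < 10) abort("n_samples must be >= 10", "anchorsig_config_error")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    abort("censoring_fraction must lie in [0, 1)", "anchorsig_config_error")
  if (baseline_hazard <= 0)
    abort("baseline_hazard must be positive", "anchorsig_config_error")
  if (noise_sd <= 0) abort("noise_sd must be positive",
                           "anchorsig_config_error")
  module_size <- rep_len(as.integer(module_size), length(anchors))
  target_rho <- rep_len(as.numeric(target_rho), length(anchors))
  if (any(module_size < 2))
    abort("module sizes must be >= 2", "anchorsig_config_error")
  if (any(abs(target_rho) >= 1))
    abort("target_rho must lie strictly inside (-1, 1)",
          "anchorsig_config_error")
  if (anyDuplicated(anchors))
    abort("anchor names must be unique", "anchorsig_config_error")
  if (!is.null(signatures)) {
    stopifnot(is.data.frame(signatures),
              all(c("name", "size", "sign", "gamma") %in% colnames(signatures)))
    if (anyDuplicated(signatures$name))
      abort("signature names must be unique", "anchorsig_config_error")
    if (any(signatures$size < 2))
      abort("signature sizes must be >= 2", "anchorsig_config_error")
    if (!all(signatures$sign %in% c(-1, 1)))
      abort("signature signs must be +1 or -1", "anchorsig_config_error")
    if (any(signatures$gamma < 0))
      abort("signature strengths must be >= 0", "anchorsig_config_error")
    if (is.null(survival_signature)) survival_signature <- signatures$name[1]
    if (!survival_signature %in% signatures$name)
      abort("survival_signature not among signature names",
            "anchorsig_config_error")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    n_background_genes = as.integer(n_background_genes),
    anchors = anchors, module_size = module_size, target_rho = target_rho,
    signatures = signatures, noise_sd = noise_sd,
    signature_rho = signature_rho,
    baseline_hazard = baseline_hazard, coef_anchor = coef_anchor,
    coef_signature = coef_signature,
    survival_signature = survival_signature,
    censoring_fraction = censoring_fraction,
    tumor_normal_shift = tumor_normal_shift, stage_slope = stage_slope,
    paired_treatment_effect = paired_treatment_effect,
    seed = as.integer(seed)), class = "simulation_config")
}

# Loading that yields corr(beta * a + eps, a) = rho when eps ~ N(0, sd^2).
rho_loading <- function(rho, sd) rho * sd / sqrt(1 - rho^2)

#' Simulate an expression cohort with planted ground truth
#'
#' Generative model, per sample `s`:
#' * each anchor has latent activity `a_s ~ N(0, 1)`; the anchor gene's
#'   expression is `a_s` plus `N(0, noise_sd^2)` noise;
#' * each of its module genes is `beta * a_s + noise` with
#'   `beta = rho * noise_sd / sqrt(1 - rho^2)` so the gene's population
#'   correlation with `a` equals `target_rho`;
#' * each signature `k` has latent activity
#'   `h_ks = sign_k * gamma_k * a_s + N(0, 1)` (anchored on the first
#'   anchor), and its member genes load on `h_ks` the same way module
#'   genes load on `a_s`;
#' * background genes are pure `N(0, noise_sd^2)` noise, giving
#'   differential-expression calls an honest null set;
#' * survival time is exponential with hazard
#'   `lambda0 * exp(theta1 * a_s + theta2 * h_s)` where `h_s` is the
#'   designated survival-driving signature's activity; censoring is an
#'   independent exponential whose rate is solved numerically so the
#'   expected censored fraction matches the target;
#' * optional tumor/normal, stage, and paired pre/post labels add the
#'   configured shifts to anchor and module genes.
#'
#' The same configuration (including seed) always produces a
#' bit-identical cohort.
#'
#' @param config a [simulation_config()].
#' @return a list of class `simulated_cohort` with elements `expression`
#'   ([expression_matrix()]), `clinical` ([clinical_table()]),
#'   `true_signatures` ([gene_set_collection()] of planted signature and
#'   module gene sets), and `truth` (module membership per anchor, planted
#'   signs, latent activities, hazard coefficients).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(salt_seed(cfg$seed, "simulate"))
  n <- cfg$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  # Latent anchor activities
  a <- matrix(stats::rnorm(length(cfg$anchors) * n), ncol = n,
              dimnames = list(cfg$anchors, sample_ids))

  gene_blocks <- list(); truth_modules <- list()
  for (i in seq_along(cfg$anchors)) {
    anc <- cfg$anchors[i]
    m <- cfg$module_size[i]
    beta <- rho_loading(cfg$target_rho[i], cfg$noise_sd)
    anchor_row <- a[anc, ] + stats::rnorm(n, sd = cfg$noise_sd)
    mod <- matrix(beta * rep(a[anc, ], each = m) +
                    stats::rnorm(m * n, sd = cfg$noise_sd), nrow = m)
    ids <- sprintf("%s_MOD%03d", anc, seq_len(m))
    rownames(mod) <- ids
    gene_blocks[[anc]] <- rbind(matrix(anchor_row, nrow = 1,
                                       dimnames = list(anc, NULL)), mod)
    truth_modules[[anc]] <- ids
  }

  # Latent signature activities tied to the first anchor
  h <- NULL; sig_sets <- list()
  if (!is.null(cfg$signatures)) {
    sig <- cfg$signatures
    h <- matrix(NA_real_, nrow(sig), n,
                dimnames = list(sig$name, sample_ids))
    a1 <- a[cfg$anchors[1], ]
    for (k in seq_len(nrow(sig))) {
      h[k, ] <- sig$sign[k] * sig$gamma[k] * a1 + stats::rnorm(n)
      b <- rho_loading(cfg$signature_rho, cfg$noise_sd)
      g <- matrix(b * rep(h[k, ], each = sig$size[k]) +
                    stats::rnorm(sig$size[k] * n, sd = cfg$noise_sd),
                  nrow = sig$size[k])
      ids <- sprintf("%s_G%03d", sig$name[k], seq_len(sig$size[k]))
      rownames(g) <- ids
      gene_blocks[[paste0("sig_", sig$name[k])]] <- g
      sig_sets[[sig$name[k]]] <- ids
    }
  }

  if (cfg$n_background_genes > 0) {
    bg <- matrix(stats::rnorm(cfg$n_background_genes * n, sd = cfg$noise_sd),
                 nrow = cfg$n_background_genes)
    rownames(bg) <- sprintf("BG%05d", seq_len(cfg$n_background_genes))
    gene_blocks[["background"]] <- bg
  }

  expr <- do.call(rbind, gene_blocks)
  colnames(expr) <- sample_ids

  # Clinical labels
  clin <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  shifted_genes <- c(cfg$anchors, unlist(truth_modules, use.names = FALSE))
  if (cfg$tumor_normal_shift != 0) {
    tumor <- sample(c(TRUE, FALSE), n, replace = TRUE)
    clin$tissue_class <- ifelse(tumor, "tumor", "normal")
    expr[shifted_genes, tumor] <-
      expr[shifted_genes, tumor] + cfg$tumor_normal_shift
  }
  if (cfg$stage_slope != 0) {
    stage <- sample(1:4, n, replace = TRUE)
    clin$stage <- stage
    expr[shifted_genes, ] <- expr[shifted_genes, ] +
      rep(cfg$stage_slope * (stage - 2.5), each = length(shifted_genes))
  }
  if (cfg$paired_treatment_effect != 0) {
    # consecutive samples form pre/post pairs within a patient
    npairs <- n %/% 2
    pid <- rep(sprintf("P%04d", seq_len(npairs + n %% 2)), each = 2)[seq_len(n)]
    tp <- rep(c("pre", "post"), length.out = n)
    clin$patient_id <- pid
    clin$timepoint <- tp
    post <- tp == "post"
    expr[shifted_genes, post] <-
      expr[shifted_genes, post] + cfg$paired_treatment_effect
  }

  # Survival: exponential with log-linear hazard
  a1 <- a[cfg$anchors[1], ]
  lin <- cfg$coef_anchor * a1
  if (!is.null(h) && !is.null(cfg$survival_signature))
    lin <- lin + cfg$coef_signature * h[cfg$survival_signature, ]
  rate <- cfg$baseline_hazard * exp(lin)
  t_event <- stats::rexp(n, rate = rate)
  if (cfg$censoring_fraction > 0) {
    # E[fraction censored] = mean_s c/(c + rate_s) for independent
    # exponential censoring at rate c; solve for c.
    f <- function(logc) mean(exp(logc) / (exp(logc) + rate)) -
      cfg$censoring_fraction
    logc <- stats::uniroot(f, lower = log(min(rate)) - 20,
                           upper = log(max(rate)) + 20)$root
    t_cens <- stats::rexp(n, rate = exp(logc))
    clin$os_time <- pmin(t_event, t_cens)
    clin$os_event <- as.integer(t_event <= t_cens)
  } else {
    clin$os_time <- t_event
    clin$os_event <- 1L
  }

  truth <- list(
    modules = truth_modules,
    planted_signs = if (is.null(cfg$signatures)) NULL else
      stats::setNames(cfg$signatures$sign, cfg$signatures$name),
    anchor_activity = a,
    signature_activity = h,
    hazard = list(baseline = cfg$baseline_hazard,
                  coef_anchor = cfg$coef_anchor,
                  coef_signature = cfg$coef_signature,
                  survival_signature = cfg$survival_signature))

  all_sets <- c(sig_sets,
                stats::setNames(truth_modules,
                                paste0(names(truth_modules), "-module")))
  structure(list(
    expression = expression_matrix(expr),
    clinical = clinical_table(clin),
    true_signatures = gene_set_collection(all_sets),
    truth = truth,
    config = cfg), class = "simulated_cohort")
}

#' Fraction of censored observations in a cohort
#'
#' @param cohort a `simulated_cohort` or a [clinical_table()].
#' @return the fraction of samples with `os_event == 0`.
#' @export
censoring_rate <- function(cohort) {
  clin <- if (inherits(cohort, "simulated_cohort")) cohort$clinical else cohort
  mean(clin$os_event == 0)
}
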