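# Deterministic ranking of one sample's expression: descending value,
# ties broken by gene identifier (stable, reproducible).
rank_genes_desc <- function(values, gene_ids) {
  order(-values, gene_ids)
}

#' Single-sample GSEA enrichment scores for one sample
#'
#' Genes are ranked by expression, descending (ties broken by gene-id
#' order).  The gene at rank position `i` receives rank weight
#' `r_i = G - i + 1` (the top gene receives `G`).  For a set with `m`
#' members the score is the integrated difference between the weighted
#' in-set ECDF and the uniform out-of-set ECDF along the ranking:
#' `ES = sum_i [ P_in(i) - P_out(i) ]` with
#' `P_in(i) = sum of r_j^alpha over in-set genes at positions <= i,
#' divided by the total over all in-set genes`, and
#' `P_out(i) = (# out-of-set genes at positions <= i) / (G - m)`.
#' The score depends on the expression column only through its ranks.
#'
#' @param expr_column named numeric vector of one sample's expression
#'   (names are gene identifiers).
#' @param sets a [gene_set_collection()].
#' @param alpha rank-weight exponent (>= 0; default 0.75).
#' @return named numeric vector of per-set ES; sets with no overlap with
#'   the gene universe get `NA` and are reported in the
#'   `"failed_sets"` attribute.
#' @export
ssgsea_sample <- function(expr_column, sets, alpha = 0.75) {
  stopifnot(inherits(sets, "gene_set_collection"))
  G <- length(expr_column)
  if (G < 2) abort("need >= 2 genes", "anchorsig_input_error")
  if (is.null(names(expr_column)))
    abort("expression column must be named by gene id",
          "anchorsig_input_error")
  if (alpha < 0) abort("alpha must be >= 0", "anchorsig_config_error")
  ord <- rank_genes_desc(expr_column, names(expr_column))
  ranked_ids <- names(expr_column)[ord]
  w <- (G:1)^alpha                      # rank weight at each position
  es <- stats::setNames(rep(NA_real_, length(sets)), names(sets))
  failed <- character(0)
  for (k in seq_along(sets)) {
    members <- sets[[k]]
    inset <- ranked_ids %in% members
    m <- sum(inset)
    if (m == 0) { failed <- c(failed, names(sets)[k]); next }
    if (m == G)
      abort(sprintf("set '%s' covers the whole gene universe",
                    names(sets)[k]), "anchorsig_input_error")
    p_in <- cumsum(w * inset) / sum(w[inset])
    p_out <- cumsum(!inset) / (G - m)
    es[k] <- sum(p_in - p_out)
  }
  if (length(failed))
    msg_log(sprintf("ssGSEA: %d set(s) with no overlap: %s",
                    length(failed), paste(failed, collapse = ", ")))
  attr(es, "failed_sets") <- failed
  es
}

#' Z-normalize a numeric vector
#'
#' `(v - mean) / sd` with the sample standard deviation (n - 1).  A
#' constant vector maps to all zeros (logged) rather than NaN, so a
#' degenerate enrichment row stays usable downstream.
#'
#' @param row numeric vector of length >= 2.
#' @return z-scored vector.
#' @export
znormalize <- function(row) {
  if (length(row) < 2) abort("need >= 2 values", "anchorsig_input_error")
  s <- stats::sd(row)
  if (s == 0) {
    msg_log("znormalize: constant row mapped to zeros")
    return(rep(0, length(row)))
  }
  (row - mean(row)) / s
}

#' ssGSEA scores for all samples, with per-set z-scores
#'
#' Applies [ssgsea_sample()] column-wise, then z-normalizes every set's
#' score vector across samples; the z-scores are the quantities used for
#' stratification and correlation downstream.
#'
#' @param expr an [expression_matrix()].
#' @param sets a [gene_set_collection()].
#' @param alpha rank-weight exponent (default 0.75).
#' @return a list of class `enrichment_matrix` with elements `es`
#'   (sets x samples raw scores), `z` (same shape, z-scored per set) and
#'   `alpha`.  Sets with no overlap are dropped (logged).
#' @export
ssgsea_matrix <- function(expr, sets, alpha = 0.75) {
  es <- vapply(seq_len(ncol(expr)), function(j)
    as.numeric(ssgsea_sample(expr[, j], sets, alpha)),
    numeric(length(sets)))
  es <- matrix(es, nrow = length(sets),
               dimnames = list(names(sets), colnames(expr)))
  keep <- !apply(es, 1, anyNA)
  if (!all(keep))
    msg_log(sprintf("dropping %d set(s) without overlap", sum(!keep)))
  es <- es[keep, , drop = FALSE]
  z <- t(apply(es, 1, znormalize))
  dimnames(z) <- dimnames(es)
  structure(list(es = es, z = z, alpha = alpha),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d sets x %d samples (alpha = %g)\n",
              nrow(x$es), ncol(x$es), x$alpha))
  invisible(x)
}

# Signal-to-noise ranking metric with GSEA's variance floor: each class
# sd is floored at 0.2 * |class mean| (0.2 if the mean is also 0).
snr_metric <- function(X, cls1, cls2) {
  m1 <- rowMeans(X[, cls1, drop = FALSE])
  m2 <- rowMeans(X[, cls2, drop = FALSE])
  s1 <- apply(X[, cls1, drop = FALSE], 1, stats::sd)
  s2 <- apply(X[, cls2, drop = FALSE], 1, stats::sd)
  fix <- function(s, m) { s <- pmax(s, 0.2 * abs(m)); ifelse(s == 0, 0.2, s) }
  (m1 - m2) / (fix(s1, m1) + fix(s2, m2))
}

# Weighted Kolmogorov-Smirnov-style running-sum ES for one set, given a
# metric vector ordered to match `gene_ids` (unsorted).
gsea_es <- function(metric, gene_ids, members, weight_p = 1) {
  ord <- order(-metric, gene_ids)
  inset <- gene_ids[ord] %in% members
  m <- sum(inset)
  G <- length(metric)
  if (m == 0 || m == G) return(NA_real_)
  w <- abs(metric[ord])^weight_p
  denom <- sum(w[inset])
  p_hit <- if (denom == 0) cumsum(inset) / m else cumsum(w * inset) / denom
  p_miss <- cumsum(!inset) / (G - m)
  run <- p_hit - p_miss
  unname(run[which.max(abs(run))])
}

#' Two-class GSEA with NES and permutation FDR
#'
#' Genes are ranked by the signal-to-noise metric between the two label
#' classes (class standard deviations floored at 0.2 x |class mean|, the
#' GSEA convention).  Each set's enrichment score is the maximum
#' deviation of the weighted running sum (member increments proportional
#' to `|metric|`, uniform decrements for non-members).  A seeded
#' permutation null — phenotype label shuffles, or random gene sets of
#' matched size when a class is small — yields, per set, the normalized
#' enrichment score `NES = ES / mean(same-sign permuted ES)`, a nominal
#' p-value from the same-sign permuted fraction, and an FDR `q` from the
#' standard pooled-NES procedure.  A set is flagged significant when
#' `fdr_q < fdr_threshold` and `NES > nes_threshold`.
#'
#' @param expr an [expression_matrix()].
#' @param labels per-sample labels with exactly two levels (vector named
#'   by sample id, or in `colnames(expr)` order); the first level sorted
#'   is the "positive" class of the metric.
#' @param sets a [gene_set_collection()].
#' @param n_perm number of permutations (default 1000).
#' @param perm_mode `"phenotype"`, `"gene_set"`, or NULL to choose
#'   automatically (gene_set when a class has fewer than 7 samples).
#' @param seed integer seed.
#' @param fdr_threshold,nes_threshold significance thresholds (defaults
#'   0.25 and 1.25).
#' @return a data.frame of class `gsea_result` with columns `set`,
#'   `size`, `ES`, `NES`, `nominal_p`, `fdr_q`, `significant`; the
#'   permutation mode used is in the `"perm_mode"` attribute.
#' @export
gsea_two_class <- function(expr, labels, sets, n_perm = 1000L,
                           perm_mode = NULL, seed = 1L,
                           fdr_threshold = 0.25, nes_threshold = 1.25) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2)
    abort("labels must have exactly two levels", "anchorsig_input_error")
  cls1 <- which(labels == lv[1]); cls2 <- which(labels == lv[2])
  if (is.null(perm_mode))
    perm_mode <- if (min(length(cls1), length(cls2)) < 7) "gene_set"
                 else "phenotype"
  perm_mode <- match.arg(perm_mode, c("phenotype", "gene_set"))
  if (perm_mode == "phenotype" && (length(cls1) < 3 || length(cls2) < 3))
    abort("phenotype permutation needs >= 3 samples per class",
          "anchorsig_input_error")
  gene_ids <- rownames(expr)
  metric <- snr_metric(expr, cls1, cls2)

  sizes <- vapply(sets, function(m) sum(gene_ids %in% m), integer(1))
  usable <- sizes > 0 & sizes < length(gene_ids)
  if (any(!usable))
    msg_log(sprintf("GSEA: excluding %d set(s) without usable overlap",
                    sum(!usable)))
  use_sets <- sets[usable]; use_sizes <- sizes[usable]
  es_obs <- vapply(use_sets, function(m)
    gsea_es(metric, gene_ids, m), numeric(1))

  set.seed(salt_seed(seed, "gsea_permute"))
  n_use <- length(use_sets)
  es_perm <- matrix(NA_real_, n_use, n_perm)
  if (perm_mode == "phenotype") {
    nc1 <- length(cls1)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(ncol(expr))
      pm <- snr_metric(expr, idx[seq_len(nc1)], idx[-seq_len(nc1)])
      es_perm[, b] <- vapply(use_sets, function(m)
        gsea_es(pm, gene_ids, m), numeric(1))
    }
  } else {
    for (k in seq_len(n_use)) {
      es_perm[k, ] <- vapply(seq_len(n_perm), function(b)
        gsea_es(metric, gene_ids,
                sample(gene_ids, use_sizes[k])), numeric(1))
    }
  }

  norm_by_sign <- function(es, perm) {
    # divide positive scores by the mean positive permuted score and
    # negative by the mean |negative| permuted score
    pos_mean <- mean(perm[perm > 0], na.rm = TRUE)
    neg_mean <- mean(abs(perm[perm < 0]), na.rm = TRUE)
    ifelse(es >= 0, es / pos_mean, es / neg_mean)
  }
  nes <- numeric(n_use); pval <- numeric(n_use)
  nes_perm <- matrix(NA_real_, n_use, n_perm)
  for (k in seq_len(n_use)) {
    perm <- es_perm[k, ]
    nes[k] <- norm_by_sign(es_obs[k], perm)
    nes_perm[k, ] <- norm_by_sign(perm, perm)
    same <- if (es_obs[k] >= 0) perm[perm >= 0] else perm[perm < 0]
    pval[k] <- if (length(same) == 0) 1
               else mean(abs(same) >= abs(es_obs[k]))
  }

  # pooled-NES FDR: for a positive NES, the ratio of the permuted-tail
  # fraction to the observed-tail fraction (capped at 1); mirrored for
  # negative NES
  all_perm <- as.vector(nes_perm); all_perm <- all_perm[is.finite(all_perm)]
  fdr <- vapply(seq_len(n_use), function(k) {
    v <- nes[k]
    if (!is.finite(v)) return(NA_real_)
    if (v >= 0) {
      denom_perm <- mean(all_perm >= 0)
      num <- if (denom_perm > 0) mean(all_perm >= v) / denom_perm else 0
      den <- mean(nes[is.finite(nes)] >= v) /
        max(mean(nes[is.finite(nes)] >= 0), 1 / n_use)
    } else {
      denom_perm <- mean(all_perm < 0)
      num <- if (denom_perm > 0) mean(all_perm <= v) / denom_perm else 0
      den <- mean(nes[is.finite(nes)] <= v) /
        max(mean(nes[is.finite(nes)] < 0), 1 / n_use)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  out <- data.frame(set = names(use_sets), size = use_sizes, ES = es_obs,
                    NES = nes, nominal_p = pval, fdr_q = fdr,
                    significant = is.finite(nes) & fdr < fdr_threshold &
                      nes > nes_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "perm_mode") <- perm_mode
  class(out) <- c("gsea_result", class(out))
  out
}
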