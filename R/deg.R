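#' Parameters for SAM-based DEG selection
#'
#' @param n_permutations number of label permutations (>= 100).  When the
#'   total number of distinct high/low label arrangements is at most this,
#'   all arrangements are enumerated exhaustively instead.
#' @param s0_method how to choose the exchangeability (fudge) factor
#'   `s0`: `"median"` (median of the per-gene pooled standard errors),
#'   `"tusher"` (coefficient-of-variation minimization over percentile
#'   windows of `s`), or `"fixed"`.
#' @param s0_value the value used when `s0_method = "fixed"`.
#' @param q_threshold per-gene FDR threshold for selection, in (0, 1].
#' @param r_threshold Pearson correlation prefilter cutoff; genes with
#'   `|r| > r_threshold` against the anchor enter SAM.
#' @param seed integer seed for the permutation draw.
#' @return a list of class `sam_params`.
#' @export
sam_params <- function(n_permutations = 1000L, s0_method = c("median",
                       "tusher", "fixed"), s0_value = 0,
                       q_threshold = 0.05, r_threshold = 0.2, seed = 1L) {
  s0_method <- match.arg(s0_method)
  if (n_permutations < 100)
    abort("n_permutations must be >= 100", "anchorsig_config_error")
  if (q_threshold <= 0 || q_threshold > 1)
    abort("q_threshold must lie in (0, 1]", "anchorsig_config_error")
  if (s0_value < 0) abort("s0_value must be >= 0", "anchorsig_config_error")
  structure(list(n_permutations = as.integer(n_permutations),
                 s0_method = s0_method, s0_value = s0_value,
                 q_threshold = q_threshold, r_threshold = r_threshold,
                 seed = as.integer(seed)), class = "sam_params")
}

#' Pearson product-moment correlation
#'
#' Thin, contract-checked wrapper around the standard product-moment
#' formula; every correlation in the package flows through this one
#' implementation.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abort("pearson_r needs two equal-length vectors of length >= 3",
          "anchorsig_stat_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("correlation undefined for a constant vector",
          "anchorsig_stat_error")
  stats::cor(x, y)
}

#' Correlation prefilter against an anchor gene
#'
#' Computes the Pearson correlation of every other gene with the anchor
#' gene's expression (over all samples) and keeps genes with
#' `|r| > threshold` (strict).  Genes with zero variance are skipped with
#' a logged count; the anchor itself never appears in the output.
#'
#' @param expr an [expression_matrix()].
#' @param anchor gene identifier present in `expr`.
#' @param threshold correlation cutoff (default 0.2).
#' @return data.frame with columns `gene_id`, `r`, ordered by decreasing
#'   `|r|`.
#' @export
correlation_prefilter <- function(expr, anchor, threshold = 0.2) {
  if (!anchor %in% rownames(expr))
    abort(paste0("anchor gene not in expression matrix: ", anchor),
          "anchorsig_input_error")
  av <- expr[anchor, ]
  if (stats::sd(av) == 0)
    abort("anchor expression is constant", "anchorsig_stat_error")
  others <- expr[setdiff(rownames(expr), anchor), , drop = FALSE]
  sds <- apply(others, 1, stats::sd)
  if (any(sds == 0))
    msg_log(sprintf("skipped %d constant gene(s) in prefilter",
                    sum(sds == 0)))
  others <- others[sds > 0, , drop = FALSE]
  r <- as.vector(stats::cor(t(others), av))
  keep <- abs(r) > threshold
  if (!any(keep))
    abort(sprintf(
      "no genes pass |r| > %g against %s; review the threshold",
      threshold, anchor), "anchorsig_input_error")
  out <- data.frame(gene_id = rownames(others)[keep], r = r[keep],
                    stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' SAM moderated difference statistic
#'
#' `d = (mean(high) - mean(low)) / (s + s0)` where
#' `s = sqrt(((1/n1 + 1/n2) / (n1 + n2 - 2)) * (SS_high + SS_low))` and
#' `SS` is the within-group sum of squared deviations.  With `s0 = 0`
#' this is the pooled-variance two-sample t statistic.
#'
#' @param high_values,low_values numeric vectors, each of length >= 2.
#' @param s0 exchangeability factor >= 0.
#' @return the statistic `d`.
#' @export
sam_statistic <- function(high_values, low_values, s0 = 0) {
  n1 <- length(high_values); n2 <- length(low_values)
  if (n1 < 2 || n2 < 2)
    abort("each group needs >= 2 samples", "anchorsig_stat_error")
  ss <- sum((high_values - mean(high_values))^2) +
    sum((low_values - mean(low_values))^2)
  s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * ss)
  (mean(high_values) - mean(low_values)) / (s + s0)
}

# Vectorized per-gene (numerator, pooled se) over a gene x sample matrix.
sam_stats_matrix <- function(X, hi) {
  n1 <- sum(hi); n2 <- sum(!hi)
  m1 <- rowMeans(X[, hi, drop = FALSE])
  m2 <- rowMeans(X[, !hi, drop = FALSE])
  ss <- rowSums((X[, hi, drop = FALSE] - m1)^2) +
    rowSums((X[, !hi, drop = FALSE] - m2)^2)
  list(num = m1 - m2, s = sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * ss))
}

# Tusher-style s0: among percentiles of s, minimize the coefficient of
# variation of the window-wise MADs of d.
choose_s0 <- function(num, s, method, fixed) {
  if (method == "fixed") return(fixed)
  if (method == "median") return(stats::median(s))
  cand <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05),
                                 names = FALSE))
  qwin <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.01),
                                 names = FALSE))
  win <- cut(s, breaks = unique(c(-Inf, qwin, Inf)))
  cv <- vapply(cand, function(s0) {
    d <- num / (s + s0)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[!is.na(mads) & mads > 0]
    if (length(mads) < 2) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  cand[which.min(cv)]
}

# All distinct assignments of n1 "high" labels among n samples, as a
# logical matrix (arrangements x n); NULL if there are more than cap.
exhaustive_labelings <- function(n, n1, cap) {
  total <- choose(n, n1)
  if (total > cap) return(NULL)
  idx <- utils::combn(n, n1)
  out <- matrix(FALSE, ncol(idx), n)
  for (b in seq_len(ncol(idx))) out[b, idx[, b]] <- TRUE
  out
}

#' SAM selection of genes up-regulated in the high group
#'
#' Runs the two-class unpaired SAM procedure on a candidate expression
#' matrix and a high/low stratification, calling only the positive
#' (up-in-high) side:
#'
#' 1. observed statistics `d_i` are computed with a data-driven `s0` and
#'    sorted; 2. high/low labels are permuted (exhaustively when the
#'    number of distinct arrangements is at most `n_permutations`,
#'    otherwise by a seeded random draw), each permutation yielding a
#'    sorted vector of statistics whose mean across permutations gives
#'    the expected order statistics `dbar_i`; 3. for a grid of thresholds
#'    `Delta`, the called set is the genes with `d_i - dbar_i >= Delta`
#'    and `d_i > 0`, the false-call estimate is the median across
#'    permutations of the number of permuted statistics at or above the
#'    smallest called `d`, and a gene's `q` is the smallest
#'    false/called ratio over the `Delta` that admit it (`pi0` fixed at
#'    1, conservative); 4. `q` is made monotone along the ranking by a
#'    cumulative minimum, and genes with `q <= q_threshold` are selected.
#'
#' @param expr_candidates [expression_matrix()] restricted to candidate
#'   genes (samples may be a superset of the stratified ones).
#' @param strat a [mean_sem_split()] result.
#' @param params a [sam_params()].
#' @param anchor optional anchor name used to label the selected set
#'   (`"<anchor>-DEG"`).
#' @param direction `"up"` (default) calls genes up-regulated in the
#'   high group; `"down"` calls the symmetric other side by exchanging
#'   the group labels, so the reported `d` is then oriented
#'   low-minus-high and the selected set is named `"<anchor>-DEG-down"`.
#' @return a list of class `deg_result`: `anchor`, `table` (data.frame
#'   with `gene_id`, `d`, `dbar`, `q`, `selected`), `selected` (a
#'   [gene_set_collection()] with the single selected set, or NULL if
#'   empty), `n_high`, `n_low`, `s0`, `n_permutations_used`,
#'   `exhaustive`.
#' @export
sam_select_up <- function(expr_candidates, strat, params = sam_params(),
                          anchor = "anchor", direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(strat, "stratify_result"))
  if (direction == "down") {
    # the d statistic is antisymmetric in the group labels, so the down
    # side is the up side with high and low exchanged
    swapped <- strat
    swapped$high_ids <- strat$low_ids
    swapped$low_ids <- strat$high_ids
    strat <- swapped
  }
  hi_ids <- intersect(strat$high_ids, colnames(expr_candidates))
  lo_ids <- intersect(strat$low_ids, colnames(expr_candidates))
  if (length(hi_ids) < 2 || length(lo_ids) < 2)
    abort("each stratified group needs >= 2 samples with expression",
          "anchorsig_input_error")
  X <- expr_candidates[, c(hi_ids, lo_ids), drop = FALSE]
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(rownames(expr_candidates),
                                                   c(hi_ids, lo_ids)))
  n1 <- length(hi_ids); n <- ncol(X)
  hi <- seq_len(n) <= n1
  G <- nrow(X)

  obs <- sam_stats_matrix(X, hi)
  s0 <- choose_s0(obs$num, obs$s, params$s0_method, params$s0_value)
  d <- obs$num / (obs$s + s0)

  labelings <- exhaustive_labelings(n, n1, params$n_permutations)
  exhaustive <- !is.null(labelings)
  if (!exhaustive) {
    set.seed(salt_seed(params$seed, "sam_permute"))
    labelings <- t(vapply(seq_len(params$n_permutations), function(b) {
      v <- rep(FALSE, n); v[sample.int(n, n1)] <- TRUE; v
    }, logical(n)))
  }
  B <- nrow(labelings)
  if (B < 2 || all(apply(labelings, 1, function(v) identical(v, hi))))
    abort("degenerate labels: permutations are all identical",
          "anchorsig_input_error")

  perm_sorted <- matrix(NA_real_, B, G)
  for (b in seq_len(B)) {
    pb <- sam_stats_matrix(X, labelings[b, ])
    perm_sorted[b, ] <- sort(pb$num / (pb$s + s0))
  }
  dbar <- colMeans(perm_sorted)

  ord <- order(d)                      # ascending; position i <-> dbar_i
  d_sorted <- d[ord]
  diff <- d_sorted - dbar

  pos <- which(d_sorted > 0)
  q_sorted <- rep(1, G)
  if (length(pos)) {
    grid <- sort(unique(diff[pos]))
    for (delta in grid) {
      called <- pos[diff[pos] >= delta]
      if (!length(called)) next
      cutoff <- min(d_sorted[called])
      false_calls <- stats::median(rowSums(perm_sorted >= cutoff))
      fdr <- min(1, false_calls / length(called))
      q_sorted[called] <- pmin(q_sorted[called], fdr)
    }
    # monotone along the ranking: a more extreme gene's q never exceeds
    # that of a less extreme one (cumulative minimum carried from the
    # least significant gene toward the most significant)
    q_sorted[pos] <- cummin(q_sorted[pos])
  }

  q <- numeric(G); q[ord] <- q_sorted
  dbar_gene <- numeric(G); dbar_gene[ord] <- dbar
  selected <- d > 0 & q <= params$q_threshold
  tab <- data.frame(gene_id = rownames(X), d = d, dbar = dbar_gene, q = q,
                    selected = selected, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$d), , drop = FALSE]
  rownames(tab) <- NULL
  set_name <- paste0(anchor, "-DEG", if (direction == "down") "-down")
  structure(list(
    anchor = anchor, table = tab,
    selected = if (any(selected))
      gene_set_collection(stats::setNames(list(rownames(X)[selected]),
                                          set_name)) else NULL,
    n_high = length(hi_ids), n_low = length(lo_ids), s0 = s0,
    n_permutations_used = B, exhaustive = exhaustive),
    class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf(
    "SAM result for %s: %d/%d genes selected (s0=%.4g, %d permutations%s)\n",
    x$anchor, sum(x$table$selected), nrow(x$table), x$s0,
    x$n_permutations_used, if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

#' Build per-anchor DEG gene sets
#'
#' For each anchor gene: stratify samples by the anchor's expression with
#' the mean +/- SEM rule, prefilter genes by `|r| > r_threshold` against
#' the anchor over all samples, then run SAM on the high/low groups and
#' keep the genes significantly up-regulated in the anchor-high group as
#' the set `"<anchor>-DEG"`.  Anchors whose pipeline fails (no
#' candidates, degenerate stratification, empty selection) are skipped
#' with a logged reason.
#'
#' @param expr an [expression_matrix()].
#' @param anchors character vector of anchor gene identifiers.
#' @param params a [sam_params()].
#' @return a list with `sets` (a [gene_set_collection()] of the
#'   successful DEG sets) and `results` (per-anchor `deg_result` or the
#'   skip reason).
#' @export
build_deg_sets <- function(expr, anchors, params = sam_params()) {
  missing <- setdiff(anchors, rownames(expr))
  if (length(missing))
    abort(paste("anchors not in expression matrix:",
                paste(missing, collapse = ", ")), "anchorsig_input_error")
  results <- list(); sets <- list(); descs <- character(0)
  for (anc in anchors) {
    res <- tryCatch({
      strat <- mean_sem_split(expr[anc, ])
      cand <- correlation_prefilter(expr, anc, params$r_threshold)
      dr <- sam_select_up(expr[cand$gene_id, , drop = FALSE], strat,
                          params, anchor = anc)
      dr$table$r <- cand$r[match(dr$table$gene_id, cand$gene_id)]
      dr$table <- dr$table[, c("gene_id", "r", "d", "dbar", "q", "selected")]
      dr
    }, anchorsig_error = function(e) {
      msg_log(sprintf("anchor %s skipped: %s", anc, conditionMessage(e)))
      conditionMessage(e)
    })
    results[[anc]] <- res
    if (inherits(res, "deg_result") && !is.null(res$selected)) {
      nm <- paste0(anc, "-DEG")
      sets[[nm]] <- res$selected[[1]]
      descs <- c(descs, sprintf("SAM up-in-high DEG set for %s", anc))
    } else if (inherits(res, "deg_result")) {
      msg_log(sprintf("anchor %s: empty DEG selection", anc))
    }
  }
  if (!length(sets))
    abort("no anchor produced a DEG set", "anchorsig_input_error")
  list(sets = gene_set_collection(sets, descs), results = results)
}
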