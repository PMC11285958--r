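# Independent brute-force oracles, written as literal translations of the
# definitions (loops, explicit vectors) so they share no code with the
# package implementations they check.

# Pooled-SE moderated statistic for one gene, from first principles.
oracle_sam_stat <- function(hi, lo, s0) {
  n1 <- length(hi); n2 <- length(lo)
  ss <- sum((hi - mean(hi))^2) + sum((lo - mean(lo))^2)
  s <- sqrt(((1 / n1 + 1 / n2) / (n1 + n2 - 2)) * ss)
  (mean(hi) - mean(lo)) / (s + s0)
}

# Full exhaustive SAM on a small matrix: enumerates every distinct
# assignment of n1 "high" labels, materializes all sorted permuted
# statistic vectors, and evaluates the Delta grid literally.
oracle_sam <- function(X, n1, s0 = NULL, q_threshold = 0.05) {
  n <- ncol(X); G <- nrow(X)
  stat_all <- function(hi_idx) {
    sapply(seq_len(G), function(g)
      oracle_sam_stat(X[g, hi_idx], X[g, -hi_idx], s0))
  }
  # s0 default: median of per-gene pooled standard errors on observed labels
  if (is.null(s0)) {
    s_obs <- sapply(seq_len(G), function(g) {
      hi <- X[g, seq_len(n1)]; lo <- X[g, -seq_len(n1)]
      ss <- sum((hi - mean(hi))^2) + sum((lo - mean(lo))^2)
      sqrt(((1 / n1 + 1 / (n - n1)) / (n - 2)) * ss)
    })
    s0 <- median(s_obs)
  }
  d <- stat_all(seq_len(n1))
  combos <- combn(n, n1)
  perm_sorted <- matrix(NA_real_, ncol(combos), G)
  for (b in seq_len(ncol(combos)))
    perm_sorted[b, ] <- sort(stat_all(combos[, b]))
  dbar_pos <- colMeans(perm_sorted)
  ord <- order(d)
  d_sorted <- d[ord]
  diffs <- d_sorted - dbar_pos
  q_sorted <- rep(1, G)
  pos <- which(d_sorted > 0)
  if (length(pos)) {
    for (delta in sort(unique(diffs[pos]))) {
      called <- pos[diffs[pos] >= delta]
      if (length(called) == 0) next
      cutoff <- min(d_sorted[called])
      counts <- numeric(nrow(perm_sorted))
      for (b in seq_len(nrow(perm_sorted)))
        counts[b] <- sum(perm_sorted[b, ] >= cutoff)
      fdr <- min(1, median(counts) / length(called))
      for (i in called) q_sorted[i] <- min(q_sorted[i], fdr)
    }
    for (i in seq_along(pos)[-1])
      q_sorted[pos[i]] <- min(q_sorted[pos[i]], q_sorted[pos[i - 1]])
  }
  q <- numeric(G); q[ord] <- q_sorted
  dbar <- numeric(G); dbar[ord] <- dbar_pos
  list(d = d, dbar = dbar, q = q, s0 = s0,
       selected = which(d > 0 & q <= q_threshold))
}

# ssGSEA for one set by materializing both ECDF vectors explicitly.
oracle_ssgsea <- function(values, members, alpha) {
  G <- length(values)
  ord <- order(-values, names(values))
  ids <- names(values)[ord]
  rank_weight <- rev(seq_len(G))          # G at the top position
  in_set <- ids %in% members
  m <- sum(in_set)
  p_in <- numeric(G); p_out <- numeric(G)
  denom_in <- sum(rank_weight[in_set]^alpha)
  for (i in seq_len(G)) {
    p_in[i] <- sum(rank_weight[seq_len(i)][in_set[seq_len(i)]]^alpha) /
      denom_in
    p_out[i] <- sum(!in_set[seq_len(i)]) / (G - m)
  }
  sum(p_in - p_out)
}

# Two-class GSEA running sum for one set, literal loop version.
oracle_gsea_es <- function(metric, gene_ids, members, p = 1) {
  ord <- order(-metric, gene_ids)
  ids <- gene_ids[ord]; met <- metric[ord]
  in_set <- ids %in% members
  G <- length(ids); m <- sum(in_set)
  nr <- sum(abs(met[in_set])^p)
  run <- numeric(G); acc <- 0
  for (i in seq_len(G)) {
    acc <- if (in_set[i]) acc + abs(met[i])^p / nr else acc - 1 / (G - m)
    run[i] <- acc
  }
  run[which.max(abs(run))]
}

# Two-group log-rank by tabulating every risk set by hand.
oracle_logrank2 <- function(t1, e1, t2, e2) {
  evt <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in evt) {
    n1 <- sum(t1 >= t); n2 <- sum(t2 >= t); n <- n1 + n2
    d1 <- sum(t1 == t & e1 == 1); d2 <- sum(t2 == t & e2 == 1)
    d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n - d) / (n - 1) * n1 * n2 / n^2
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Product-limit survival by hand at given times.
oracle_km <- function(times, events, at) {
  sapply(at, function(t0) {
    s <- 1
    for (t in sort(unique(times[events == 1 & times <= t0]))) {
      n <- sum(times >= t); d <- sum(times == t & events == 1)
      s <- s * (1 - d / n)
    }
    s
  })
}
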