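#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator over the distinct observed
#' times.  At tied times, events are processed before censorings (the
#' standard convention), so a censoring at an event time is still at
#' risk for that event.
#'
#' @param times positive observation times.
#' @param events event indicators (1 = death observed, 0 = censored).
#' @param group optional label carried through to the output.
#' @return a data.frame of class `km_curve` with columns `time` (distinct
#'   observed times, ascending), `n_risk`, `n_event`, `n_censor`,
#'   `surv` (step-function value just after `time`), and a `"group"`
#'   attribute.
#' @export
km_estimate <- function(times, events, group = NULL) {
  if (length(times) != length(events) || length(times) < 1)
    abort("times and events must be equal-length, non-empty",
          "anchorsig_input_error")
  if (any(times <= 0))
    abort("non-positive survival time", "anchorsig_input_error")
  if (!all(events %in% c(0, 1)))
    abort("events must be 0/1", "anchorsig_input_error")
  tt <- sort(unique(times))
  n_risk <- n_event <- n_censor <- integer(length(tt))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    at_risk <- sum(times >= tt[i])
    d <- sum(times == tt[i] & events == 1)
    cns <- sum(times == tt[i] & events == 0)
    s <- s * (1 - d / at_risk)
    n_risk[i] <- at_risk; n_event[i] <- d; n_censor[i] <- cns
    surv[i] <- s
  }
  out <- data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv)
  attr(out, "group") <- group
  class(out) <- c("km_curve", class(out))
  out
}

# Survival probability at time t from a km_curve (right-continuous step).
km_surv_at <- function(curve, t) {
  idx <- which(curve$time <= t)
  if (!length(idx)) 1 else curve$surv[max(idx)]
}

#' k-group log-rank test
#'
#' At each distinct event time the observed events per group are
#' compared with their expectation under the null (total events times
#' the group's share of the risk set), with the hypergeometric
#' covariance; the chi-square statistic is the quadratic form of the
#' observed-minus-expected vector (dropping one group) against the
#' summed covariance, on `k - 1` degrees of freedom.
#'
#' @param groups a list of `k >= 2` elements, each a list/data.frame
#'   with `times` and `events`.
#' @return a list of class `logrank_result` with `chi2`, `df`, `p`,
#'   `observed`, `expected`, `n` (per-group sizes).
#' @export
logrank <- function(groups) {
  k <- length(groups)
  if (k < 2) abort("need >= 2 groups", "anchorsig_input_error")
  times <- lapply(groups, function(g) g$times)
  events <- lapply(groups, function(g) g$events)
  if (any(lengths(times) == 0))
    abort("every group needs >= 1 subject", "anchorsig_input_error")
  all_t <- unlist(times); all_e <- unlist(events)
  if (sum(all_e) == 0)
    abort("no events observed in any group", "anchorsig_input_error")
  if (any(all_t <= 0))
    abort("non-positive survival time", "anchorsig_input_error")
  evt_times <- sort(unique(all_t[all_e == 1]))
  O <- vapply(events, sum, numeric(1))
  E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in evt_times) {
    n_j <- vapply(times, function(tv) sum(tv >= t), numeric(1))
    d_j <- vapply(seq_len(k), function(j)
      sum(times[[j]] == t & events[[j]] == 1), numeric(1))
    n <- sum(n_j); d <- sum(d_j)
    if (n == 0 || d == 0) next
    E <- E + d * n_j / n
    if (n > 1) {
      fac <- d * (n - d) / (n - 1)
      for (j in seq_len(k)) for (l in seq_len(k))
        V[j, l] <- V[j, l] +
          fac * (n_j[j] / n) * ((j == l) - n_j[l] / n)
    }
  }
  oe <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chi2 <- tryCatch(as.numeric(t(oe) %*% solve(Vk, oe)),
                   error = function(e) {
                     # singular covariance (e.g. a group with no risk
                     # overlap): use a pseudo-inverse
                     sv <- svd(Vk)
                     pos <- sv$d > max(sv$d) * 1e-12
                     vi <- sv$v[, pos, drop = FALSE] %*%
                       diag(1 / sv$d[pos], sum(pos)) %*%
                       t(sv$u[, pos, drop = FALSE])
                     as.numeric(t(oe) %*% vi %*% oe)
                   })
  df <- k - 1L
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 observed = O, expected = E,
                 n = lengths(times)), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi2 = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

# Pull (times, events) for a set of sample ids from a clinical table.
surv_subset <- function(clin, ids) {
  rows <- clin[match(intersect(ids, clin$sample_id), clin$sample_id), ,
               drop = FALSE]
  rows <- rows[!is.na(rows$os_time) & !is.na(rows$os_event), , drop = FALSE]
  list(times = rows$os_time, events = rows$os_event)
}

#' Two-group survival comparison from a stratification
#'
#' Aligns the high/low groups of a [mean_sem_split()] with a clinical
#' table (the excluded middle band never enters), estimates a
#' Kaplan-Meier curve per group, and tests the difference with the
#' two-group log-rank test.
#'
#' @param strat a `stratify_result`.
#' @param clin a [clinical_table()].
#' @return a list with `km_high`, `km_low` ([km_estimate()] curves) and
#'   `logrank` ([logrank()] result).
#' @export
survival_by_stratification <- function(strat, clin) {
  stopifnot(inherits(strat, "stratify_result"))
  hi <- surv_subset(clin, strat$high_ids)
  lo <- surv_subset(clin, strat$low_ids)
  if (length(hi$times) < 2 || length(lo$times) < 2)
    abort("each stratified group needs >= 2 clinical records",
          "anchorsig_input_error")
  list(km_high = km_estimate(hi$times, hi$events, group = "high"),
       km_low = km_estimate(lo$times, lo$events, group = "low"),
       logrank = logrank(list(hi, lo)))
}

#' Combined four-group survival analysis
#'
#' Crosses two stratifications (for example anchor expression and a
#' signature's enrichment z-score) into HH/HL/LH/LL groups, estimates a
#' Kaplan-Meier curve per group, runs the overall four-group log-rank
#' test (3 df), and reports all six pairwise two-group log-rank tests
#' with raw p-values (no multiplicity correction; the pairwise p-values
#' are descriptive).
#'
#' @param strat_gene,strat_signature `stratify_result` objects.
#' @param clin a [clinical_table()].
#' @return a list with `groups` (sample -> label), `km` (named list of 4
#'   curves), `overall` ([logrank()] result) and `pairwise` (data.frame
#'   of pairwise chi2/p).
#' @export
combined_survival <- function(strat_gene, strat_signature, clin) {
  groups <- four_group_assign(strat_gene, strat_signature)
  labs <- c("HH", "HL", "LH", "LL")
  subsets <- lapply(labs, function(g)
    surv_subset(clin, names(groups)[groups == g]))
  names(subsets) <- labs
  if (any(vapply(subsets, function(s) length(s$times), integer(1)) < 2))
    abort("four-group survival needs >= 2 clinical records per group",
          "anchorsig_input_error")
  km <- lapply(labs, function(g)
    km_estimate(subsets[[g]]$times, subsets[[g]]$events, group = g))
  names(km) <- labs
  pairs <- utils::combn(labs, 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   chi2 = NA_real_, p = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    lr <- tryCatch(logrank(subsets[pairs[, i]]),
                   anchorsig_error = function(e) NULL)
    if (!is.null(lr)) { pw$chi2[i] <- lr$chi2; pw$p[i] <- lr$p }
  }
  list(groups = groups, km = km, overall = logrank(subsets), pairwise = pw)
}
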