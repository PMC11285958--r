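#' Dichotomize samples by the mean +/- SEM rule
#'
#' Samples with score at or above `mean + SEM` form the high group, those
#' at or below `mean - SEM` the low group, and the middle band is
#' excluded.  SEM is the sample standard deviation (n - 1 denominator)
#' divided by `sqrt(n)`.  The rule is location- and positive-scale
#' invariant, and the same rule serves raw expression values and
#' enrichment z-scores.
#'
#' @param values named numeric vector of per-sample scores (names are
#'   sample identifiers; if unnamed, indices are used).
#' @return a list of class `stratify_result` with elements `high_ids`,
#'   `low_ids`, `excluded_ids`, `mean`, `sem`, `threshold_high`,
#'   `threshold_low`.
#' @export
mean_sem_split <- function(values) {
  if (length(values) < 4)
    abort("mean/SEM stratification needs at least 4 samples",
          "anchorsig_stratify_error")
  if (is.null(names(values))) names(values) <- as.character(seq_along(values))
  if (anyDuplicated(names(values)))
    abort("duplicate sample identifiers", "anchorsig_stratify_error")
  if (stats::sd(values) == 0)
    abort("degenerate stratification: all values identical",
          "anchorsig_stratify_error")
  m <- mean(values)
  sem <- stats::sd(values) / sqrt(length(values))
  hi <- m + sem; lo <- m - sem
  high <- names(values)[values >= hi]
  low <- names(values)[values <= lo]
  if (length(high) == 0 || length(low) == 0)
    abort(sprintf(
      "empty stratification group at thresholds low=%.6g, high=%.6g",
      lo, hi), "anchorsig_stratify_error")
  structure(list(
    high_ids = high, low_ids = low,
    excluded_ids = setdiff(names(values), c(high, low)),
    mean = m, sem = sem, threshold_high = hi, threshold_low = lo),
    class = "stratify_result")
}

#' @export
print.stratify_result <- function(x, ...) {
  cat(sprintf(
    "mean+/-SEM split: %d high, %d low, %d excluded (thresholds %.4g / %.4g)\n",
    length(x$high_ids), length(x$low_ids), length(x$excluded_ids),
    x$threshold_low, x$threshold_high))
  invisible(x)
}

#' Combine two stratifications into four groups
#'
#' Samples non-excluded under both stratifiers are assigned HH, HL, LH,
#' or LL: the first letter is the status under `a`, the second under
#' `b`.  All four groups must be non-empty for a four-group survival
#' comparison to be defined.
#'
#' @param a,b `stratify_result` objects over overlapping sample sets.
#' @return named character vector mapping sample id to group label.
#' @export
four_group_assign <- function(a, b) {
  stopifnot(inherits(a, "stratify_result"), inherits(b, "stratify_result"))
  in_a <- c(stats::setNames(rep("H", length(a$high_ids)), a$high_ids),
            stats::setNames(rep("L", length(a$low_ids)), a$low_ids))
  in_b <- c(stats::setNames(rep("H", length(b$high_ids)), b$high_ids),
            stats::setNames(rep("L", length(b$low_ids)), b$low_ids))
  shared <- intersect(names(in_a), names(in_b))
  groups <- stats::setNames(paste0(in_a[shared], in_b[shared]), shared)
  sizes <- table(factor(groups, levels = c("HH", "HL", "LH", "LL")))
  msg_log(paste("four-group sizes:",
                paste(names(sizes), sizes, sep = "=", collapse = ", ")))
  if (any(sizes == 0))
    abort(paste0("empty four-group cell(s): ",
                 paste(names(sizes)[sizes == 0], collapse = ", "),
                 " (sizes ", paste(sizes, collapse = "/"), ")"),
          "anchorsig_stratify_error")
  groups
}

#' Write a stratification assignment for audit
#'
#' @param groups named character vector (e.g. from [four_group_assign()]),
#'   or a `stratify_result`.
#' @param path output TSV path.
#' @export
write_stratification <- function(groups, path) {
  if (inherits(groups, "stratify_result")) {
    groups <- c(
      stats::setNames(rep("high", length(groups$high_ids)), groups$high_ids),
      stats::setNames(rep("low", length(groups$low_ids)), groups$low_ids),
      stats::setNames(rep("excluded", length(groups$excluded_ids)),
                      groups$excluded_ids))
  }
  utils::write.table(
    data.frame(sample_id = names(groups), group = unname(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
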