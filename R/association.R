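#' Correlate a predictor with every signature's z-scores
#'
#' Pearson correlation of a per-sample predictor (anchor expression or a
#' DEG set's enrichment z-score) against each signature row of an
#' enrichment matrix, over their shared samples.
#'
#' @param predictor named numeric vector (names are sample ids).
#' @param enr an [ssgsea_matrix()] result.
#' @return named numeric vector of per-signature `r`; rows with
#'   undefined correlation are `NA` (flagged in the log).
#' @export
correlate_predictor_signatures <- function(predictor, enr) {
  stopifnot(inherits(enr, "enrichment_matrix"))
  shared <- intersect(names(predictor), colnames(enr$z))
  if (length(shared) < 3)
    abort("need >= 3 shared samples", "anchorsig_input_error")
  p <- predictor[shared]
  out <- vapply(rownames(enr$z), function(s) {
    zrow <- enr$z[s, shared]
    if (stats::sd(zrow) == 0 || stats::sd(p) == 0) return(NA_real_)
    pearson_r(p, zrow)
  }, numeric(1))
  if (anyNA(out))
    msg_log(sprintf("%d signature(s) with undefined correlation",
                    sum(is.na(out))))
  out
}

#' Build a correlation profile for several predictors
#'
#' @param predictors named list of per-sample numeric vectors.
#' @param enr an [ssgsea_matrix()] result.
#' @param dataset_tag label for the cohort the profile came from.
#' @return a signatures x predictors matrix of Pearson `r` of class
#'   `correlation_profile` with a `"dataset_tag"` attribute.
#' @export
correlation_profile <- function(predictors, enr, dataset_tag = "") {
  stopifnot(is.list(predictors), !is.null(names(predictors)))
  prof <- vapply(predictors, function(p)
    correlate_predictor_signatures(p, enr), numeric(nrow(enr$z)))
  prof <- matrix(prof, nrow = nrow(enr$z),
                 dimnames = list(rownames(enr$z), names(predictors)))
  structure(prof, dataset_tag = dataset_tag,
            class = c("correlation_profile", "matrix"))
}

#' Classify signatures as positive or negative by summed correlation
#'
#' Sums each signature's correlations over every profile and predictor;
#' signatures with a positive sum are "positive", a negative sum
#' "negative", and an exact zero is left unassigned (logged).  An
#' average-linkage hierarchical clustering of the signatures on
#' `1 - cor` distance between their correlation rows supplies a display
#' ordering for heatmaps; the operative classification is the sign of
#' the sum.
#'
#' @param profiles a [correlation_profile()] or list of them sharing
#'   signature names.
#' @return a list of class `signature_classification`: `positive`,
#'   `negative`, `unassigned`, `sum_r` (named vector), `order` (leaf
#'   order, when computable).
#' @export
classify_signatures <- function(profiles) {
  if (inherits(profiles, "correlation_profile")) profiles <- list(profiles)
  if (!length(profiles))
    abort("need at least one correlation profile", "anchorsig_input_error")
  sig <- rownames(profiles[[1]])
  for (p in profiles)
    if (!identical(rownames(p), sig))
      abort("profiles must share signature names (same order)",
            "anchorsig_input_error")
  stacked <- do.call(cbind, lapply(profiles, unclass))
  sum_r <- rowSums(stacked, na.rm = TRUE)
  unassigned <- names(sum_r)[sum_r == 0]
  if (length(unassigned))
    msg_log(sprintf("%d signature(s) with zero summed r left unassigned",
                    length(unassigned)))
  leaf_order <- NULL
  if (nrow(stacked) >= 3 && ncol(stacked) >= 2) {
    cc <- suppressWarnings(stats::cor(t(stacked), use = "pairwise"))
    cc[!is.finite(cc)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    leaf_order <- sig[hc$order]
  }
  structure(list(positive = names(sum_r)[sum_r > 0],
                 negative = names(sum_r)[sum_r < 0],
                 unassigned = unassigned, sum_r = sum_r,
                 order = leaf_order),
            class = "signature_classification")
}

#' @export
print.signature_classification <- function(x, ...) {
  cat(sprintf("signature classification: %d positive, %d negative%s\n",
              length(x$positive), length(x$negative),
              if (length(x$unassigned))
                sprintf(", %d unassigned", length(x$unassigned)) else ""))
  invisible(x)
}

#' Two-tailed Student's t-test (pooled variance or paired)
#'
#' Unpaired: pooled-variance Student t with `df = n1 + n2 - 2` (not
#' Welch).  Paired: t on the within-pair differences, `df = n - 1`.
#'
#' @param a,b numeric vectors.
#' @param paired logical.
#' @return list with `t`, `df`, `p` (two-sided), `mean_a`, `mean_b`.
#' @export
student_t_test <- function(a, b, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b) || length(a) < 2)
      abort("paired test needs equal lengths >= 2", "anchorsig_stat_error")
    if (stats::sd(a - b) == 0)
      abort("zero variance of paired differences", "anchorsig_stat_error")
    ht <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (length(a) < 2 || length(b) < 2)
      abort("each group needs >= 2 values", "anchorsig_stat_error")
    if (stats::var(a) + stats::var(b) == 0)
      abort("zero pooled variance", "anchorsig_stat_error")
    ht <- stats::t.test(a, b, var.equal = TRUE)
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Monotone trend of a score across ordinal tumor stages
#'
#' Spearman rank correlation (mid-ranks for ties) between the score and
#' stage, with the t-approximation p-value.  The per-stage displays this
#' summarizes do not name a trend statistic; Spearman is the natural
#' choice for an ordinal covariate.
#'
#' @param values per-sample numeric scores.
#' @param stages ordinal stages (integers 1-4), same length.
#' @return list with `rho` and `p`.
#' @export
stage_trend <- function(values, stages) {
  stopifnot(length(values) == length(stages))
  ok <- !is.na(values) & !is.na(stages)
  values <- values[ok]; stages <- stages[ok]
  if (length(values) < 5)
    abort("need >= 5 samples with stage", "anchorsig_input_error")
  if (length(unique(stages)) < 2)
    abort("need >= 2 distinct stages", "anchorsig_input_error")
  ht <- suppressWarnings(stats::cor.test(values, stages,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value)
}

#' Compare a score between two clinical groups
#'
#' Dispatches a contrast named in the clinical table to the Student
#' t-test: `tumor_vs_normal` on `tissue_class`,
#' `primary_vs_metastatic`, `pre_vs_post`, and `primary_vs_recurrent`
#' on `timepoint`.  Longitudinal contrasts (`pre_vs_post`,
#' `primary_vs_recurrent`) pair samples by `patient_id` when complete
#' pairs exist, otherwise fall back to the unpaired test.
#'
#' @param values named numeric vector of per-sample scores.
#' @param clin a [clinical_table()].
#' @param contrast one of `"tumor_vs_normal"`, `"primary_vs_metastatic"`,
#'   `"pre_vs_post"`, `"primary_vs_recurrent"`.
#' @return list with the test result plus `contrast`, `levels`, `n`,
#'   `paired`, and `direction` (sign of the first-minus-second group
#'   mean difference).
#' @export
contrast_groups <- function(values, clin,
                            contrast = c("tumor_vs_normal",
                                         "primary_vs_metastatic",
                                         "pre_vs_post",
                                         "primary_vs_recurrent")) {
  contrast <- match.arg(contrast)
  spec <- switch(contrast,
    tumor_vs_normal = list(col = "tissue_class",
                           levels = c("tumor", "normal"), pairable = FALSE),
    primary_vs_metastatic = list(col = "timepoint",
                                 levels = c("primary", "metastatic"),
                                 pairable = FALSE),
    pre_vs_post = list(col = "timepoint", levels = c("pre", "post"),
                       pairable = TRUE),
    primary_vs_recurrent = list(col = "timepoint",
                                levels = c("primary", "recurrent"),
                                pairable = TRUE))
  if (!spec$col %in% colnames(clin))
    abort(paste0("clinical table lacks column ", spec$col),
          "anchorsig_input_error")
  clin <- clin[clin$sample_id %in% names(values), , drop = FALSE]
  g1 <- clin$sample_id[clin[[spec$col]] %in% spec$levels[1]]
  g2 <- clin$sample_id[clin[[spec$col]] %in% spec$levels[2]]
  if (!length(g1) || !length(g2))
    abort(sprintf("contrast level missing: %s=%d, %s=%d",
                  spec$levels[1], length(g1), spec$levels[2], length(g2)),
          "anchorsig_input_error")
  paired <- FALSE
  if (spec$pairable && "patient_id" %in% colnames(clin)) {
    p1 <- clin$patient_id[match(g1, clin$sample_id)]
    p2 <- clin$patient_id[match(g2, clin$sample_id)]
    shared <- intersect(p1, p2)
    shared <- shared[!is.na(shared)]
    if (length(shared) >= 2) {
      g1 <- g1[match(shared, p1)]
      g2 <- g2[match(shared, p2)]
      paired <- TRUE
    }
  }
  res <- student_t_test(values[g1], values[g2], paired = paired)
  c(res, list(contrast = contrast, levels = spec$levels,
              n = c(length(g1), length(g2)), paired = paired,
              direction = sign(res$mean_a - res$mean_b)))
}
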