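test_that("Student t-test matches hand-computed values", {
  r <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)

  same <- student_t_test(c(1, 2, 3), c(1, 2, 3) + 1e-14)
  expect_equal(same$t, 0, tolerance = 1e-6)
  expect_equal(same$p, 1, tolerance = 1e-6)

  # paired differences (2, 3, 4) - (1, 1, 1) = (1, 2, 3)
  pr <- student_t_test(c(2, 3, 4), c(1, 1, 1), paired = TRUE)
  expect_equal(pr$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(pr$t, 3.464102, tolerance = 1e-6)
  expect_equal(pr$df, 2)

  expect_error(student_t_test(c(1, 1), c(1, 1)),
               class = "anchorsig_stat_error")
})

test_that("predictor-signature correlation identifies planted signs", {
  cohort <- quick_cohort(seed = 4, n = 500, module = 10, background = 120,
                         signatures = small_sig_frame(2, 2, size = 25,
                                                      gamma = 0.5))
  enr <- ssgsea_matrix(cohort$expression, signature_sets(cohort), 0.75)
  anchor_expr <- cohort$expression["JAG1", ]
  r <- correlate_predictor_signatures(anchor_expr, enr)
  expect_true(all(r[c("POSSIG1", "POSSIG2")] > 0))
  expect_true(all(r[c("NEGSIG1", "NEGSIG2")] < 0))

  # a predictor equal to a z row correlates perfectly with it
  r_self <- correlate_predictor_signatures(enr$z["POSSIG1", ], enr)
  expect_equal(unname(r_self["POSSIG1"]), 1, tolerance = 1e-12)

  # an independent predictor stays weakly correlated with everything
  set.seed(99)
  r_null <- correlate_predictor_signatures(
    setNames(rnorm(500), colnames(cohort$expression)), enr)
  expect_lt(max(abs(r_null)), 0.2)
})

test_that("classify_signatures uses the sign of the summed correlation", {
  prof <- structure(matrix(0.3, 4, 2,
                           dimnames = list(sprintf("S%d", 1:4), c("p1", "p2"))),
                    dataset_tag = "x",
                    class = c("correlation_profile", "matrix"))
  cl <- classify_signatures(prof)
  expect_setequal(cl$positive, sprintf("S%d", 1:4))
  expect_length(cl$negative, 0)

  # negating every correlation flips every classification
  neg <- prof; neg[] <- -neg
  cl_neg <- classify_signatures(neg)
  expect_setequal(cl_neg$negative, cl$positive)

  # order of the profiles does not matter
  set.seed(10)
  p1 <- prof; p1[] <- rnorm(8); p2 <- prof; p2[] <- rnorm(8)
  expect_equal(classify_signatures(list(p1, p2))$sum_r,
               classify_signatures(list(p2, p1))$sum_r)
})

test_that("planted positive and negative signatures are classified correctly", {
  cohort <- quick_cohort(seed = 20, n = 500, module = 10, background = 100,
                         signatures = small_sig_frame(5, 5, size = 20,
                                                      gamma = 0.5))
  enr <- ssgsea_matrix(cohort$expression, signature_sets(cohort), 0.75)
  prof <- correlation_profile(list(JAG1 = cohort$expression["JAG1", ]), enr)
  cl <- classify_signatures(prof)
  truth <- cohort$truth$planted_signs
  recovered <- sum(names(truth)[truth > 0] %in% cl$positive) +
    sum(names(truth)[truth < 0] %in% cl$negative)
  expect_gte(recovered, 9)
})

test_that("stage_trend detects monotone trends and rejects single stages", {
  st <- c(1, 1, 2, 2, 3, 3, 4, 4)
  # rank-perfect trend (ties in the values mirror the stage ties)
  r <- stage_trend(10 * st, st)
  expect_equal(r$rho, 1, tolerance = 1e-12)
  # strictly increasing values across tied stages stay strongly positive
  r2 <- stage_trend(1:8, st)
  expect_gt(r2$rho, 0.9)
  expect_error(stage_trend(1:8, rep(2, 8)), class = "anchorsig_input_error")

  cohort <- quick_cohort(seed = 6, n = 400, module = 10, background = 20,
                         stage_slope = 0.5)
  tr <- stage_trend(cohort$expression["JAG1", ], cohort$clinical$stage)
  expect_gt(tr$rho, 0)
  expect_lt(tr$p, 0.05)
})

test_that("contrast_groups detects planted shifts and pairs by patient", {
  cohort <- quick_cohort(seed = 7, n = 400, module = 10, background = 20,
                         tumor_normal_shift = 1)
  res <- contrast_groups(cohort$expression["JAG1", ], cohort$clinical,
                         "tumor_vs_normal")
  expect_gt(res$mean_a - res$mean_b, 0)
  expect_lt(res$p, 0.001)
  expect_false(res$paired)

  paired <- quick_cohort(seed = 8, n = 100, module = 10, background = 20,
                         paired_treatment_effect = 0.5)
  pres <- contrast_groups(paired$expression["JAG1", ], paired$clinical,
                          "pre_vs_post")
  expect_true(pres$paired)
  expect_lt(pres$mean_a - pres$mean_b, 0)   # post is higher
  expect_lt(pres$p, 0.05)

  expect_error(contrast_groups(cohort$expression["JAG1", ], cohort$clinical,
                               "pre_vs_post"),
               class = "anchorsig_input_error")
})
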