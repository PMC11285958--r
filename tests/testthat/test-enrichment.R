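test_that("ssGSEA reproduces the worked 4-gene example", {
  v <- setNames(c(4, 3, 2, 1), c("A", "B", "C", "D"))
  sets <- gene_set_collection(list(TOP = "A"))
  es <- ssgsea_sample(v, sets, alpha = 1)
  # running differences 1, 2/3, 1/3, 0 sum to 2
  expect_equal(unname(es["TOP"]), 2.0, tolerance = 1e-12)
})

test_that("ssGSEA matches the explicit-ECDF brute force on random instances", {
  set.seed(5)
  for (i in 1:30) {
    G <- sample(10:60, 1)
    ids <- sprintf("g%03d", seq_len(G))
    v <- setNames(rnorm(G), ids)
    m <- sample(2:(G - 2), 1)
    members <- sample(ids, m)
    alpha <- sample(c(0, 0.25, 0.75, 1), 1)
    sets <- gene_set_collection(list(S = members))
    es <- unname(ssgsea_sample(v, sets, alpha)["S"])
    expect_equal(es, oracle_ssgsea(v, members, alpha), tolerance = 1e-10)
  }
})

test_that("ssGSEA extremal and invariance properties", {
  set.seed(6)
  G <- 30
  ids <- sprintf("g%03d", seq_len(G))
  v <- setNames(sort(rnorm(G), decreasing = TRUE), ids)
  m <- 5
  top_set <- ids[1:m]
  es_top <- unname(ssgsea_sample(v, gene_set_collection(list(S = top_set)),
                                 0.75)["S"])
  for (i in 1:10) {
    other <- sample(ids, m)
    es_o <- unname(ssgsea_sample(v, gene_set_collection(list(S = other)),
                                 0.75)["S"])
    expect_lte(es_o, es_top + 1e-12)
  }
  # rank-only dependence: strictly monotone transforms leave ES unchanged
  vv <- setNames(rnorm(G), ids)
  sets <- gene_set_collection(list(S = sample(ids, 8)))
  base <- ssgsea_sample(vv, sets, 0.75)
  expect_equal(ssgsea_sample(exp(vv), sets, 0.75), base, tolerance = 1e-12)
  expect_equal(ssgsea_sample(rank(vv), sets, 0.75), base, tolerance = 1e-12)
  # each partial difference lies in [-1, 1], so |ES| <= G
  expect_lte(abs(base[["S"]]), G)

  # whole-universe sets are rejected; zero-overlap sets are flagged
  expect_error(ssgsea_sample(vv, gene_set_collection(list(S = ids)), 1),
               class = "anchorsig_input_error")
  es_na <- suppressMessages(
    ssgsea_sample(vv, gene_set_collection(list(S = c("zz1", "zz2"))), 1))
  expect_true(is.na(es_na[["S"]]))
})

test_that("znormalize centers, scales, and handles constant rows", {
  expect_equal(znormalize(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(suppressMessages(znormalize(rep(4, 6))), rep(0, 6))
  set.seed(8)
  v <- znormalize(rnorm(50))
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(sd(v), 1, tolerance = 1e-12)
})

test_that("ssgsea_matrix z-scores rows and is sample-order equivariant", {
  cohort <- quick_cohort(seed = 2, n = 40, background = 60,
                         signatures = small_sig_frame(2, 2, size = 15))
  sets <- signature_sets(cohort)
  enr <- ssgsea_matrix(cohort$expression, sets, 0.75)
  expect_equal(dim(enr$es), c(length(sets), 40))
  expect_true(all(abs(rowMeans(enr$z)) < 1e-10))
  expect_equal(unname(apply(enr$z, 1, sd)), rep(1, nrow(enr$z)),
               tolerance = 1e-10)

  perm <- sample(ncol(cohort$expression))
  enr_p <- ssgsea_matrix(cohort$expression[, perm], sets, 0.75)
  expect_equal(enr_p$es, enr$es[, perm], tolerance = 1e-12)

  # duplicated sample columns give identical ES and an all-zero z row
  two <- cohort$expression[, c(1, 1)]
  colnames(two) <- c("X1", "X2")
  enr2 <- suppressMessages(ssgsea_matrix(two, sets, 0.75))
  expect_equal(enr2$es[, 1], enr2$es[, 2], ignore_attr = TRUE)
  expect_true(all(enr2$z == 0))
})

test_that("planted signature activity is recovered by ssGSEA z-scores", {
  cohort <- quick_cohort(seed = 12, n = 500, module = 10, background = 150,
                         signatures = small_sig_frame(1, 0, size = 50,
                                                      gamma = 0.5))
  enr <- ssgsea_matrix(cohort$expression, signature_sets(cohort), 0.75)
  h <- cohort$truth$signature_activity["POSSIG1", ]
  expect_gt(cor(enr$z["POSSIG1", ], h), 0.6)
})

test_that("two-class GSEA: extremal set, brute-force ES, antisymmetry", {
  set.seed(14)
  G <- 80; n <- 24
  ids <- sprintf("g%03d", 1:G)
  X <- expression_matrix(matrix(rnorm(G * n), G,
                                dimnames = list(ids, sprintf("s%02d", 1:n))))
  labels <- rep(c("a", "b"), each = n / 2)
  metric <- anchorsig:::snr_metric(X, 1:(n / 2), (n / 2 + 1):n)

  topk <- ids[order(-metric)][1:8]
  sets <- gene_set_collection(list(TOPK = topk,
                                   R1 = sample(ids, 8), R2 = sample(ids, 8)))
  res <- gsea_two_class(X, labels, sets, n_perm = 100, seed = 1)
  expect_gt(res$ES[res$set == "TOPK"], 0)
  expect_equal(which.max(res$ES), which(res$set == "TOPK"))

  # ES agrees with the literal running-sum loop
  for (i in 1:20) {
    members <- sample(ids, sample(3:20, 1))
    expect_equal(anchorsig:::gsea_es(metric, ids, members),
                 oracle_gsea_es(metric, ids, members), tolerance = 1e-10)
  }

  # swapping the class labels negates the metric and every ES
  res_sw <- gsea_two_class(X, setNames(rev(labels), colnames(X)), sets,
                           n_perm = 100, seed = 1)
  expect_equal(res_sw$ES, -res$ES, tolerance = 1e-10)
})

test_that("GSEA null calibration stays below the significance thresholds", {
  set.seed(3)
  frac <- replicate(3, {
    G <- 150; n <- 30
    ids <- sprintf("g%03d", 1:G)
    X <- expression_matrix(matrix(rnorm(G * n), G,
                                  dimnames = list(ids,
                                                  sprintf("s%02d", 1:n))))
    sets <- gene_set_collection(
      setNames(lapply(1:10, function(i) sample(ids, 15)),
               sprintf("SET%02d", 1:10)))
    labels <- rep(c("a", "b"), each = n / 2)
    res <- suppressMessages(gsea_two_class(X, labels, sets, n_perm = 200,
                                           seed = sample.int(1e6, 1)))
    mean(res$significant)
  })
  expect_lte(mean(frac), 0.25)
})
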