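test_that("pearson_r matches hand computation and rejects degenerate input", {
  x <- c(1, 5, 3, 9, 2)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_r(x, rep(1, 5)), class = "anchorsig_stat_error")
  expect_error(pearson_r(1:2, 1:2), class = "anchorsig_stat_error")
})

test_that("sam_statistic matches worked values and t-statistic identity", {
  d0 <- sam_statistic(c(4, 5, 6), c(1, 2, 3), s0 = 0)
  expect_equal(d0, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(d0, 3.674235, tolerance = 1e-6)
  expect_equal(sam_statistic(c(1, 2, 3), c(1, 2, 3), 0), 0)
  d1 <- sam_statistic(c(4, 5, 6), c(1, 2, 3), s0 = 1)
  expect_equal(d1, 3 / (sqrt(2 / 3) + 1), tolerance = 1e-12)
  expect_lt(abs(d1), abs(d0))

  # with s0 = 0 the statistic is the pooled-variance two-sample t
  set.seed(11)
  for (i in 1:25) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), mean = 1)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(sam_statistic(a, b, 0), unname(tt$statistic),
                 tolerance = 1e-10)
  }
})

test_that("correlation prefilter recovers a planted module and excludes the anchor", {
  cohort <- quick_cohort(seed = 3, n = 500, module = 40, rho = 0.5,
                         background = 200)
  cand <- correlation_prefilter(cohort$expression, "JAG1", 0.2)
  expect_false("JAG1" %in% cand$gene_id)
  module <- cohort$truth$modules$JAG1
  recall <- mean(module %in% cand$gene_id)
  expect_gte(recall, 0.95)
  expect_true(all(abs(cand$r) > 0.2))

  expect_error(correlation_prefilter(cohort$expression, "JAG1", 1.0),
               class = "anchorsig_input_error")
  expect_error(correlation_prefilter(cohort$expression, "NOPE"),
               class = "anchorsig_input_error")
})

test_that("sam_select_up finds a planted shift and honors the q threshold", {
  set.seed(21)
  n1 <- n2 <- 30
  G <- 51
  X <- matrix(rnorm(G * (n1 + n2)), G,
              dimnames = list(sprintf("g%02d", 1:G),
                              sprintf("s%02d", 1:(n1 + n2))))
  X[1, 1:n1] <- X[1, 1:n1] + 3      # 3 sd shift in the high group
  strat <- structure(list(high_ids = colnames(X)[1:n1],
                          low_ids = colnames(X)[(n1 + 1):(n1 + n2)],
                          excluded_ids = character(0)),
                     class = "stratify_result")
  res <- sam_select_up(X, strat, sam_params(n_permutations = 500, seed = 5),
                       anchor = "test")
  expect_true("g01" %in% res$selected[[1]])
  expect_lte(res$table$q[res$table$gene_id == "g01"], 0.05)
  # every selected gene is up in the high group
  expect_true(all(res$table$d[res$table$selected] > 0))

  # a vanishing threshold empties the selection
  res0 <- sam_select_up(X, strat,
                        sam_params(n_permutations = 500, seed = 5,
                                   q_threshold = 1e-12), anchor = "test")
  expect_lte(sum(res0$table$selected),
             sum(res0$table$q <= 1e-12))
})

test_that("sam_select_up is deterministic under a fixed seed", {
  set.seed(9)
  X <- matrix(rnorm(20 * 40), 20,
              dimnames = list(sprintf("g%02d", 1:20),
                              sprintf("s%02d", 1:40)))
  strat <- structure(list(high_ids = colnames(X)[1:20],
                          low_ids = colnames(X)[21:40],
                          excluded_ids = character(0)),
                     class = "stratify_result")
  p <- sam_params(n_permutations = 200, seed = 42)
  r1 <- sam_select_up(X, strat, p)
  r2 <- sam_select_up(X, strat, p)
  expect_identical(r1$table, r2$table)
})

test_that("exhaustive SAM matches the brute-force enumerator", {
  set.seed(31)
  for (i in 1:10) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    G <- sample(4:8, 1)
    X <- matrix(rnorm(G * (n1 + n2)), G,
                dimnames = list(sprintf("g%d", 1:G),
                                sprintf("s%d", 1:(n1 + n2))))
    strat <- structure(list(high_ids = colnames(X)[1:n1],
                            low_ids = colnames(X)[(n1 + 1):(n1 + n2)],
                            excluded_ids = character(0)),
                       class = "stratify_result")
    res <- sam_select_up(X, strat,
                         sam_params(n_permutations = 300,
                                    s0_method = "median"))
    expect_true(res$exhaustive)
    orc <- oracle_sam(X, n1, s0 = NULL)
    tab <- res$table[match(rownames(X), res$table$gene_id), ]
    expect_equal(tab$d, orc$d, tolerance = 1e-9)
    expect_equal(tab$dbar, orc$dbar, tolerance = 1e-9)
    expect_equal(tab$q, orc$q, tolerance = 1e-9)
  }
})

test_that("the down side mirrors the up side on sign-flipped data", {
  set.seed(77)
  X <- matrix(rnorm(6 * 8), 6,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:8)))
  X[1, 1:4] <- X[1, 1:4] - 2
  strat <- structure(list(high_ids = colnames(X)[1:4],
                          low_ids = colnames(X)[5:8],
                          excluded_ids = character(0)),
                     class = "stratify_result")
  p <- sam_params(n_permutations = 300, s0_method = "fixed", s0_value = 0.1)
  down <- sam_select_up(X, strat, p, anchor = "A", direction = "down")
  up_neg <- sam_select_up(-X, strat, p, anchor = "A")
  expect_true(down$exhaustive)
  tab_d <- down$table[order(down$table$gene_id), ]
  tab_u <- up_neg$table[order(up_neg$table$gene_id), ]
  expect_equal(tab_d$d, tab_u$d, tolerance = 1e-12)
  expect_equal(tab_d$q, tab_u$q, tolerance = 1e-12)
  expect_equal(names(down$selected), "A-DEG-down")
})

test_that("build_deg_sets recovers planted modules and skips null anchors", {
  cohort <- simulate_cohort(simulation_config(
    n_samples = 200, n_background_genes = 300,
    anchors = c("JAG1", "NOTCH1"), module_size = c(40, 40),
    target_rho = c(0.5, 0.5), seed = 17))
  res <- suppressMessages(build_deg_sets(
    cohort$expression, c("JAG1", "NOTCH1"),
    sam_params(n_permutations = 200, seed = 3)))
  expect_true(all(c("JAG1-DEG", "NOTCH1-DEG") %in% names(res$sets)))
  for (anc in c("JAG1", "NOTCH1")) {
    sel <- res$sets[[paste0(anc, "-DEG")]]
    truth <- cohort$truth$modules[[anc]]
    f1 <- 2 * length(intersect(sel, truth)) / (length(sel) + length(truth))
    expect_gte(f1, 0.7)
  }

  # an anchor with no co-expressed module yields no DEG set but the
  # informative anchors still succeed
  cohort0 <- simulate_cohort(simulation_config(
    n_samples = 200, n_background_genes = 300,
    anchors = c("JAG1", "DLL3"), module_size = c(40, 10),
    target_rho = c(0.5, 0.0), seed = 23))
  res0 <- suppressMessages(build_deg_sets(
    cohort0$expression, c("JAG1", "DLL3"),
    sam_params(n_permutations = 200, seed = 3)))
  expect_true("JAG1-DEG" %in% names(res0$sets))
  expect_false("DLL3-DEG" %in% names(res0$sets))
})
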