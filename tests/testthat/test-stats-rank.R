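# Rank statistics against hand computations, brute-force enumeration and
# base R's independent implementations.

test_that("spearman_rho matches hand computation and the rank-then-correlate oracle", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  set.seed(11)
  for (i in 1:20) {
    x <- sample(1:4, 5, replace = TRUE)  # ties likely
    y <- sample(1:4, 5, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(spearman_rho(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("spearman exact permutation p agrees with cor.test on tie-free input", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:7, 1)
    x <- sample(100, n)
    y <- sample(100, n)
    ours <- spearman_rho(x, y, exact = TRUE)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = TRUE))
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
  # n = 3 monotone: only the two extreme orderings reach |rho| = 1
  expect_equal(spearman_rho(1:3, 1:3)$p_value, 2 / 6, tolerance = 1e-12)
})

test_that("spearman is invariant under strictly increasing transforms", {
  set.seed(31)
  x <- rnorm(15)
  y <- rnorm(15)
  base <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y)$rho, base$rho)
  expect_equal(spearman_rho(x, y^3 + 5 * y)$rho, base$rho)
  expect_equal(spearman_rho(rank(x), y)$rho, base$rho)
})

test_that("constant input gives an undefined-result signal, not a number", {
  res <- spearman_rho(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(res$undefined)
  expect_true(is.na(res$rho))
  expect_true(is.na(res$p_value))
})

test_that("kruskal_wallis reproduces hand ranks and base R on random inputs", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(round(res$statistic, 3), 3.857)
  # two identical groups: perfectly symmetric ranks
  sym <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  set.seed(41)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) sample(1:6, sample(2:6, 1),
                                                    replace = TRUE))
    if (length(unique(unlist(groups))) == 1) next
    ours <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(groups)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter))
  }
})

test_that("kruskal_wallis flags fully tied data as degenerate", {
  res <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_true(res$degenerate)
  expect_true(is.na(res$statistic))
})

test_that("chi-square p is close to the exact permutation p at N = 9", {
  set.seed(51)
  diffs <- numeric(5)
  for (i in 1:5) {
    groups <- list(sample(20, 3), sample(20, 3), sample(20, 3))
    res <- kruskal_wallis(groups, exact = TRUE)
    expect_equal(res$p_exact, oracle_kw_exact(groups), tolerance = 1e-12)
    diffs[i] <- abs(res$p_value - res$p_exact)
  }
  # the chi-square approximation tracks the exact permutation p at N = 9
  expect_lt(median(diffs), 0.05)
})

test_that("dunn_pairwise matches the hand z formula and is structurally sound", {
  set.seed(61)
  groups <- list(a = rnorm(4), b = rnorm(5) + 1, c = rnorm(3) - 1)
  res <- dunn_pairwise(groups)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(res$z_matrix[i, j], oracle_dunn_z(groups, i, j),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(res$p_matrix))
  expect_equal(unname(diag(res$p_matrix)), rep(1, 3))
  # two identical groups: zero mean-rank difference
  same <- dunn_pairwise(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$p_matrix[1, 2], 1)
})

test_that("holm adjustment only increases p-values and preserves their order", {
  set.seed(71)
  groups <- lapply(1:4, function(j) rnorm(5, mean = j / 2))
  raw <- dunn_pairwise(groups, adjust = "none")$p_matrix
  adj <- dunn_pairwise(groups, adjust = "holm")$p_matrix
  up <- upper.tri(raw)
  expect_true(all(adj[up] >= raw[up] - 1e-15))
  ord <- order(raw[up])
  expect_true(all(diff(adj[up][ord]) >= -1e-15))
})

test_that("mann_whitney_u exact p matches enumeration and wilcox.test", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(mann_whitney_u(c(5, 6, 7), c(5, 6, 7))$p_value, 1)
  set.seed(81)
  for (i in 1:10) {
    a <- sample(1:8, 4, replace = TRUE)
    b <- sample(1:8, 4, replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$p_value, oracle_mwu_exact(a, b),
                 tolerance = 1e-12)
  }
  for (i in 1:10) {
    vals <- sample(100, 11)  # distinct across both samples: no ties
    a <- vals[1:5]
    b <- vals[6:11]
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(mann_whitney_u(a, b)$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal-approximation p is within 0.02 of exact p at n = 6 + 6", {
  set.seed(91)
  for (i in 1:10) {
    a <- rnorm(6)
    b <- rnorm(6, mean = 0.5)
    p_exact <- mann_whitney_u(a, b, exact = TRUE)$p_value
    p_norm <- mann_whitney_u(a, b, exact = FALSE)$p_value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("hpd_interval equals the brute-force narrowest window", {
  expect_equal(hpd_interval(0:999, 0.95), c(lower = 0, upper = 949))
  expect_equal(hpd_interval(rep(3.5, 25)), c(lower = 3.5, upper = 3.5))
  set.seed(101)
  for (i in 1:15) {
    n <- sample(20:1000, 1)
    x <- rlnorm(n)  # skewed
    expect_equal(unname(hpd_interval(x, 0.9)), oracle_hpd(x, 0.9))
  }
})

test_that("HPD of a skewed sample is no wider than the equal-tail interval", {
  set.seed(111)
  x <- rgamma(2000, shape = 2)
  h <- hpd_interval(x, 0.95)
  q <- stats::quantile(x, c(0.025, 0.975))
  expect_lte(h[["upper"]] - h[["lower"]], unname(q[2] - q[1]) + 1e-12)
})
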