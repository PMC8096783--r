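test_that("kappa: closed-form anchors, bands, and error contract", {
  a <- rep(c(TRUE, FALSE), 10)
  k1 <- cohen_kappa(a, a)
  expect_equal(k1$kappa, 1)
  expect_equal(k1$label, "almost perfect")

  # 2x2 table [[40,10],[10,40]]: p_o = 0.8, p_e = 0.5, kappa = 0.6
  x <- rep(c(TRUE, TRUE, FALSE, FALSE), c(40, 10, 10, 40))
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 10, 40))
  k2 <- cohen_kappa(x, y)
  expect_equal(k2$kappa, 0.6, tolerance = 1e-12)
  expect_equal(k2$label, "substantial")
  se <- sqrt(0.8 * 0.2 / (100 * 0.25))
  expect_equal(k2$ci_low, 0.6 - qnorm(0.975) * 2 * se / 2, tolerance = 1e-10)

  expect_equal(landis_koch(0.83), "almost perfect")
  expect_equal(landis_koch(c(-0.1, 0.1, 0.3, 0.5, 0.7, 0.95)),
               c("poor", "slight", "fair", "moderate", "substantial",
                 "almost perfect"))
  expect_error(cohen_kappa(rep(TRUE, 5), rep(TRUE, 5)), "undefined")
})

test_that("kappa is symmetric, label-swap invariant, truncated to [-1, 1]", {
  set.seed(61)
  for (i in 1:10) {
    a <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    b <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (length(unique(a)) == 1 && identical(a, b)) next
    expect_equal(cohen_kappa(a, b)$kappa, cohen_kappa(b, a)$kappa)
    expect_equal(cohen_kappa(!a, !b)$kappa, cohen_kappa(a, b)$kappa)
    k <- cohen_kappa(a, b)
    expect_gte(k$ci_low, -1); expect_lte(k$ci_high, 1)
    expect_lte(k$ci_low, k$kappa); expect_gte(k$ci_high, k$kappa)
  }
})

test_that("kappa point estimate matches an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(62)
  for (i in 1:5) {
    a <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    b <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    ours <- cohen_kappa(a, b)$kappa
    theirs <- e1071::classAgreement(table(a, b))$kappa
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("Fisher exact p equals hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 3, 7, 7), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-10)
  t2 <- matrix(c(1, 9, 9, 1), 2)
  expect_equal(fisher_exact_2x2(t2), enumerate_fisher(t2), tolerance = 1e-10)
  set.seed(63)
  for (i in 1:20) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), enumerate_fisher(tab), tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(fisher_exact_2x2(matrix(c(0.5, 1, 1, 1), 2)), "integer")
})

test_that("Kruskal-Wallis handles ties, nulls, and planted shifts", {
  expect_equal(kruskal_wallis(rep(1, 6), rep(1:2, 3)),
               list(H = 0, p_value = 1, df = 1))
  set.seed(64)
  v <- c(rnorm(10), rnorm(10), rnorm(10) + 10)
  g <- rep(1:3, each = 10)
  kt <- kruskal_wallis(v, g)
  expect_equal(kt$df, 2)
  expect_lt(kt$p_value, 0.01)
  expect_error(kruskal_wallis(1:3, rep(1, 3)), "2 groups")
})

test_that("CD3 PCA surrogate matches an eigen-decomposition oracle", {
  set.seed(65)
  n <- 50
  base <- rnorm(n)
  m <- rbind(CD3D = base + rnorm(n, sd = 0.3),
             CD3E = base + rnorm(n, sd = 0.3),
             CD3G = base + rnorm(n, sd = 0.3),
             CD247 = base + rnorm(n, sd = 0.3))
  colnames(m) <- paste0("S", 1:n)
  sc <- cd3_pca_score(m)
  z <- t(scale(t(m)))
  ev <- eigen(z %*% t(z) / (n - 1))
  oracle <- drop(t(z) %*% ev$vectors[, 1])
  if (cor(oracle, colMeans(z)) < 0) oracle <- -oracle
  expect_gt(abs(cor(sc, oracle)), 1 - 1e-10)
  expect_gt(cor(sc, colMeans(z)), 0)
  expect_equal(attr(sc, "explained_variance"),
               ev$values[1] / sum(ev$values), tolerance = 1e-10)
  # gene order invariance
  expect_equal(unname(cd3_pca_score(m[c(3, 1, 4, 2), ])), unname(sc))
  expect_error(cd3_pca_score(m[1, , drop = FALSE]), ">= 2")
})

test_that("rank-1 expression puts all variance on the first component", {
  v <- rnorm(20)
  m <- rbind(CD3D = v, CD3E = 2 * v + 1, CD3G = 0.5 * v - 3, CD247 = v)
  colnames(m) <- paste0("S", 1:20)
  sc <- cd3_pca_score(m)
  expect_equal(attr(sc, "explained_variance"), 1, tolerance = 1e-10)
  expect_equal(abs(cor(sc, v)), 1, tolerance = 1e-10)
})

test_that("marker dichotomization uses strict thresholds on both rules", {
  expect_equal(as.character(dichotomize_marker(c(5, 10, 15), 10)),
               c("low", "low", "high"))
  expect_equal(as.character(dichotomize_marker(c(0, 1, 50), 0)),
               c("low", "high", "high"))
  expect_true(all(dichotomize_marker(rep(7, 5), rule = "median") == "low"))
  expect_error(dichotomize_marker(numeric(0), 10), "empty")
  expect_error(dichotomize_marker(c(5, 105), 10), "\\[0, 100\\]")
})

test_that("CD45 normalization subtracts on log2 scale or ratios on linear", {
  m <- rbind(CD33 = c(4, 6), PTPRC = c(1, 2))
  colnames(m) <- c("S1", "S2")
  expect_equal(unname(cd45_normalize(m, "CD33")), c(3, 4))
  expect_equal(unname(cd45_normalize(m, "CD33", mode = "ratio")), c(8, 16))
  expect_error(cd45_normalize(m, "CD8"), "absent")
})
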