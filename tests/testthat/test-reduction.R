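test_that("KW screen filters by significance and modulation direction", {
  ids <- paste0("S", 1:20)
  pos <- rep(c(TRUE, FALSE), each = 10)
  up_in_pos <- c(rnorm(10, 3), rnorm(10, 0))
  up_in_neg <- c(rnorm(10, 0), rnorm(10, 3))
  flat <- rep(1, 20)
  m <- rbind(UP = up_in_pos, WRONGWAY = up_in_neg, FLAT = flat)
  colnames(m) <- ids
  panel <- gene_panel(c("UP", "WRONGWAY", "FLAT"), name = "p")
  st <- status_of(ids, pos)
  set.seed(1)
  res <- kw_screen(m, panel, st)
  expect_true(res$pass[res$gene == "UP"])
  # significant but modulated against the declared direction: excluded
  expect_lt(res$p[res$gene == "WRONGWAY"], 0.05)
  expect_false(res$pass[res$gene == "WRONGWAY"])
  expect_equal(res$H[res$gene == "FLAT"], 0)
  expect_false(res$pass[res$gene == "FLAT"])
  expect_error(kw_screen(m, panel, status_of(ids, rep(TRUE, 20))), "nonempty")
})

test_that("two-group KW matches the exact permutation enumeration on 3+3", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  p_exact <- enumerate_kw(x, y)
  expect_equal(p_exact, 0.1, tolerance = 1e-12)
  # chi-square approximation is reported alongside and is of the same order
  kt <- kruskal_wallis(c(x, y), rep(1:2, each = 3))
  expect_equal(kt$H, 3.857142857, tolerance = 1e-6)
  expect_lt(kt$p_value, 0.1)
})

test_that("Spearman CI: exact anchors, Fisher-z interval, strong-pair rule", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_ci(x, exp(x))$r_s, 1)
  expect_equal(spearman_ci(x, -x)$r_s, -1)
  set.seed(8)
  a <- rnorm(40); b <- a + rnorm(40, sd = 0.4)
  s <- spearman_ci(a, b)
  z <- atanh(cor(a, b, method = "spearman"))
  expect_equal(s$ci_low, tanh(z - qnorm(0.975) / sqrt(37)), tolerance = 1e-10)
  expect_identical(s$strong, s$ci_low > 0.6)
  expect_error(spearman_ci(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_ci(1:3, 1:3), "n >= 4")
})

test_that("redundancy pruning keeps one representative per correlated block", {
  expect_equal(prune_redundant(c("A", "B"), strong_pairs_tbl <- tibble::tibble(
    gene_i = character(), gene_j = character(), r_s = numeric(),
    ci_low = numeric(), ci_high = numeric(), strong = logical()))$retained,
    c("A", "B"))
  # identical duplicate: exactly one survives
  set.seed(3)
  v <- rnorm(30)
  m <- rbind(A = v, A2 = v, C = rnorm(30))
  colnames(m) <- paste0("S", 1:30)
  pr <- prune_redundant(c("A", "A2", "C"), strong_pairs(m, c("A", "A2", "C")))
  expect_setequal(pr$retained, c("A", "C"))

  for (seed in 1:5) {
    set.seed(seed)
    blocks <- lapply(1:3, function(b) {
      common <- rnorm(60)
      sapply(1:3, function(i) sqrt(0.95) * common + sqrt(0.05) * rnorm(60))
    })
    m <- t(do.call(cbind, blocks))
    rownames(m) <- sprintf("G%02d", 1:9)
    colnames(m) <- sprintf("S%02d", 1:60)
    pr <- prune_redundant(rownames(m), strong_pairs(m, rownames(m)))
    picked_blocks <- unique((match(pr$retained, rownames(m)) - 1) %/% 3)
    expect_equal(length(pr$retained), 3)
    expect_equal(sort(picked_blocks), 0:2)
  }
})

test_that("Bonferroni selection applies the alpha/m threshold", {
  expect_equal(bonferroni_select("g", 0.04, 0.05, 1), "g")
  expect_equal(bonferroni_select("g", 0.04, 0.05, 10), character(0))
  expect_equal(bonferroni_select(letters[1:3], rep(0, 3), 0.05, 1000),
               letters[1:3])
  expect_error(bonferroni_select("g", 0.5, alpha = 1.5), "alpha")
  expect_error(bonferroni_select(letters[1:3], rep(0.1, 3), m = 2), "m must")
})

test_that("concordance statistic matches a double-loop oracle", {
  set.seed(12)
  for (i in 1:5) {
    sc <- rnorm(30); pos <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (all(pos) || all(!pos)) pos[1:2] <- c(TRUE, FALSE)
    pairs <- expand.grid(p = which(pos), n = which(!pos))
    oracle <- mean(ifelse(sc[pairs$p] > sc[pairs$n], 1,
                          ifelse(sc[pairs$p] == sc[pairs$n], 0.5, 0)))
    expect_equal(concordance_stat(sc, pos), oracle, tolerance = 1e-12)
  }
})

test_that("all-subset logistic regression finds the informative gene", {
  hits <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 200
    pos <- rep(c(TRUE, FALSE), each = n / 2)
    m <- rbind(INFO = rnorm(n) + 2 * pos,
               matrix(rnorm(9 * n), 9, dimnames = list(paste0("N", 1:9), NULL)))
    colnames(m) <- paste0("S", seq_len(n))
    res <- all_subset_logistic(m, rownames(m), status_of(colnames(m), pos),
                               max_size = 3)
    identical(res$best_genes, "INFO")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("all-subset search equals an independent glm re-enumeration", {
  set.seed(44)
  n <- 80
  pos <- rep(c(TRUE, FALSE), each = n / 2)
  m <- matrix(rnorm(4 * n), 4, n,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:n)))
  m["G1", ] <- m["G1", ] + pos * 1.2
  st <- status_of(colnames(m), pos)
  res <- all_subset_logistic(m, rownames(m), st, max_size = 4)

  z <- t(scale(t(m)))
  best <- list(c = -Inf)
  for (k in 1:4) for (s in combn(rownames(m), k, simplify = FALSE)) {
    fit <- glm(pos ~ ., data = data.frame(pos = pos, t(z[s, , drop = FALSE])),
               family = binomial())
    cst <- concordance_stat(predict(fit), pos)
    if (cst > best$c + 1e-12) best <- list(c = cst, genes = s)
  }
  row <- res$subsets[res$subsets$genes == paste(best$genes, collapse = ","), ]
  expect_equal(row$concordance, best$c, tolerance = 1e-8)
  expect_equal(max(res$subsets$concordance), best$c, tolerance = 1e-8)
  expect_lte(abs(res$concordance - best$c), 0.02)  # parsimony tie-break band
})

test_that("single candidate and pure noise behave as expected", {
  set.seed(9)
  n <- 200
  pos <- rep(c(TRUE, FALSE), each = n / 2)
  m <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("A", "B"), paste0("S", 1:n)))
  one <- all_subset_logistic(m, "A", status_of(colnames(m), pos))
  expect_identical(one$best_genes, "A")
  expect_lt(abs(one$concordance - 0.5), 0.1)
})

test_that("optimal cutoff equals the full threshold scan and breaks ties low", {
  sep_scores <- c(1, 2, 3, 10, 11)
  sep_pos <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  oc <- optimal_cutoff(sep_scores, sep_pos)
  expect_equal(oc$agreement, 1)
  expect_equal(oc$cutoff, 6.5)  # lowest midpoint inside the gap
  expect_error(optimal_cutoff(rep(1, 4), c(TRUE, TRUE, FALSE, FALSE)), "constant")

  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    sc <- round(rnorm(n), 1)
    if (length(unique(sc)) == 1) next
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(pos) || all(!pos)) pos[1:2] <- c(TRUE, FALSE)
    oc <- optimal_cutoff(sc, pos)
    brute <- sapply(c(sort(unique(sc)) - 1e-9, max(sc) + 1),
                    function(t) mean((sc >= t) == pos))
    expect_equal(oc$agreement, max(brute), tolerance = 1e-12)
  }
})

test_that("full reduction keeps stage containment and is deterministic", {
  cohort <- make_cohort(n = 150, delta = 2, seed = 53)
  ec <- call_ecm3(cohort$expr, cohort$ecm, n_restarts = 50, seed = 4)
  red <- suppressMessages(reduce_signature(cohort$expr, cohort$ecm, ec$status))
  tr <- red$trace
  expect_true(all(red$signature$genes %in% tr$bonferroni_survivors))
  expect_true(all(tr$bonferroni_survivors %in% tr$pruned$retained))
  expect_true(all(tr$pruned$retained %in% tr$stage1_genes))
  red2 <- suppressMessages(reduce_signature(cohort$expr, cohort$ecm, ec$status))
  expect_identical(red$signature$genes, red2$signature$genes)
  expect_identical(red$signature$cutoff, red2$signature$cutoff)
  expect_gte(tr$agreement$kappa, 0.8)
})
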