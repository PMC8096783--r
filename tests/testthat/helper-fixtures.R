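# Shared fixtures, built in code at test time.

make_panels <- function(n_ecm = 30, n_ifn = 21) {
  list(ecm = gene_panel(sprintf("ECM%03d", seq_len(n_ecm)), name = "ECM"),
       ifn = gene_panel(sprintf("IFN%02d", seq_len(n_ifn)), name = "IFN"))
}

# Small planted cohort used across module tests.
make_cohort <- function(n = 120, delta = 2, seed = 11, ...) {
  p <- make_panels()
  sim <- simulate_expression(n, p$ecm, p$ifn, delta = delta, seed = seed, ...)
  c(sim, p)
}

# Status tibble from a plain logical vector.
status_of <- function(ids, positive, name = "sig") {
  signature_status(ids, positive, as.numeric(positive), name)
}

# Independent brute-force LAS optimum: enumerate every nonempty
# row-subset x column-subset pair, scoring directly from the normal tail.
brute_force_las <- function(X) {
  m <- nrow(X); n <- ncol(X)
  best <- list(score = -Inf)
  for (rb in seq_len(2^m - 1)) {
    rs <- which(intToBits(rb)[1:m] == 1)
    for (cb in seq_len(2^n - 1)) {
      cs <- which(intToBits(cb)[1:n] == 1)
      tau <- mean(X[rs, cs])
      sc <- -pnorm(-tau * sqrt(length(rs) * length(cs)), log.p = TRUE) -
        lchoose(m, length(rs)) - lchoose(n, length(cs))
      if (sc > best$score) best <- list(rows = rs, cols = cs, score = sc)
    }
  }
  best
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration.
enumerate_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  ks <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, N - r1, c1)
  p_obs <- dhyper(tab[1, 1], r1, N - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-group permutation p-value for the Kruskal-Wallis statistic.
enumerate_kw <- function(x, y) {
  v <- c(x, y)
  kw_h <- function(idx) {
    g <- rep(2L, length(v)); g[idx] <- 1L
    kruskal_wallis(v, g)$H
  }
  h_obs <- kw_h(seq_along(x))
  combos <- combn(length(v), length(x), simplify = FALSE)
  hs <- vapply(combos, kw_h, numeric(1))
  mean(hs >= h_obs - 1e-10)
}
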