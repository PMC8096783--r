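# Large-average-submatrix (LAS) biclustering over the ECM gene panel.
# The ECM3 subgroup is the sample set of the top-scoring positive-average
# bicluster. The score of a k x l submatrix with standardized-entry mean
# tau is
#
#   S = -log Phi(-tau * sqrt(k*l)) - log C(m,k) - log C(n,l)
#
# i.e. a Gaussian tail significance penalized by the number of submatrices
# of that size; the search alternates between the optimal gene subset for a
# fixed sample set and vice versa, from random restarts.

#' Row-standardize an expression matrix over a gene panel
#'
#' Restricts to panel genes present in the matrix (absences are logged and
#' skipped, mirroring cross-platform panels), drops constant rows with a
#' warning, and scales every retained row to mean 0, sd 1. Missing values
#' are mean-imputed per gene (i.e. set to 0 after centering) inside this
#' scoring path only; the stored data are never modified.
#'
#' @param expr genes x samples log2 matrix.
#' @param panel optional [gene_panel()]; `NULL` keeps all genes.
#' @return standardized matrix (rows: retained panel genes).
#' @export
standardize_expression <- function(expr, panel = NULL) {
  validate_expression(expr)
  if (ncol(expr) < 2) stop("need >= 2 samples")
  if (!is.null(panel)) {
    absent <- setdiff(panel$gene, rownames(expr))
    if (length(absent) > 0) {
      decif_log("panel gene(s) absent from platform, skipped: %s",
                paste(absent, collapse = ", "))
    }
    keep <- intersect(panel$gene, rownames(expr))
    expr <- expr[keep, , drop = FALSE]
  }
  mu <- rowMeans(expr, na.rm = TRUE)
  ctr <- expr - mu
  ctr[is.na(ctr)] <- 0
  s <- apply(ctr, 1, sd)
  const <- s < .Machine$double.eps^0.5
  if (any(const)) {
    warning("dropping ", sum(const), " constant gene row(s): ",
            paste(rownames(expr)[const], collapse = ", "))
    ctr <- ctr[!const, , drop = FALSE]
    s <- s[!const]
  }
  if (nrow(ctr) < 2) stop("fewer than 2 usable panel genes after filtering")
  ctr / s
}

#' LAS significance score of a submatrix
#'
#' Computed in log space with the log-scale normal tail, so it does not
#' underflow even for `tau * sqrt(k*l)` in the hundreds. Strictly increasing
#' in `tau` for fixed dimensions. Vectorized over all arguments.
#'
#' @param k,l submatrix gene and sample counts.
#' @param tau submatrix mean in standardized (z) units.
#' @param m,n total gene and sample counts.
#' @return numeric score (dimensionless log scale).
#' @export
las_score <- function(k, l, tau, m, n) {
  if (any(!is.finite(tau))) stop("non-finite tau")
  stopifnot(all(k >= 1), all(k <= m), all(l >= 1), all(l <= n))
  -pnorm(-tau * sqrt(k * l), log.p = TRUE) - lchoose(m, k) - lchoose(n, l)
}

# Given a fixed sample (column) set, the score-optimal gene set for any size
# k is the top k rows by row mean; scan all prefix sizes. Returns indices.
best_rows_for_cols <- function(X, cols) {
  rm <- rowMeans(X[, cols, drop = FALSE])
  ord <- order(rm, decreasing = TRUE)
  tau <- cumsum(rm[ord]) / seq_len(nrow(X))
  sc <- las_score(seq_len(nrow(X)), length(cols), tau, nrow(X), ncol(X))
  k <- which.max(sc)
  list(rows = sort(ord[seq_len(k)]), score = sc[k])
}

#' Search for the top large-average submatrix
#'
#' `method = "alternating"` (default) runs `n_restarts` random restarts,
#' each in two stages: first, alternating average-maximization at a fixed
#' random submatrix size (top-k genes for the current samples and top-l
#' samples for the current genes) locates a high-average basin; then
#' score-adaptive refinement re-chooses both set sizes by sorting means and
#' scanning all prefix sizes for the score optimum, iterating until the
#' sets repeat. `method = "exhaustive"` enumerates every nonempty
#' row-subset x column-subset pair (feasible up to about 12 x 12) and is
#' exact.
#'
#' @param std_expr standardized matrix from [standardize_expression()].
#' @param n_restarts random restarts (>= 1).
#' @param seed integer seed (alternating search is deterministic given it).
#' @param method `"alternating"` or `"exhaustive"`.
#' @param max_iter iteration cap per restart.
#' @return object of class `bicluster`: `gene_set`, `sample_set`, `avg`
#'   (mean of the standardized submatrix), `score`, `method`.
#' @export
las_search <- function(std_expr, n_restarts = 1000, seed = NULL,
                       method = c("alternating", "exhaustive"),
                       max_iter = 100) {
  method <- match.arg(method)
  m <- nrow(std_expr); n <- ncol(std_expr)
  if (method == "exhaustive") {
    if (m > 12 || n > 12) stop("exhaustive search limited to 12 x 12")
    best <- list(score = -Inf)
    row_sets <- lapply(seq_len(2^m - 1), function(b) which(bitwAnd(b, 2^(seq_len(m) - 1)) > 0))
    col_sets <- lapply(seq_len(2^n - 1), function(b) which(bitwAnd(b, 2^(seq_len(n) - 1)) > 0))
    for (rs in row_sets) {
      sub <- std_expr[rs, , drop = FALSE]
      cs_means <- colMeans(sub)
      for (cs in col_sets) {
        tau <- mean(cs_means[cs])
        sc <- las_score(length(rs), length(cs), tau, m, n)
        if (sc > best$score) best <- list(rows = rs, cols = cs, score = sc, avg = tau)
      }
    }
    return(new_bicluster(std_expr, best$rows, best$cols, best$score, method))
  }

  if (n_restarts < 1) stop("n_restarts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tX <- t(std_expr)
  best <- list(score = -Inf, rows = 1L, cols = 1L)
  for (r in seq_len(n_restarts)) {
    # Stage 1: average-maximization at fixed random (k, l). Starting the
    # size-adaptive scan from a random set lets the combinatorial penalty
    # collapse the search onto degenerate whole-row/single-column optima;
    # fixed-size alternation first locates the high-average basin.
    k0 <- sample(max(1L, m %/% 2), 1)
    l0 <- sample(max(1L, n %/% 2), 1)
    cols <- sort(sample(n, l0))
    rows <- integer(0)
    for (it in seq_len(max_iter)) {
      rm <- rowMeans(std_expr[, cols, drop = FALSE])
      new_rows <- sort(order(rm, decreasing = TRUE)[seq_len(k0)])
      cm <- rowMeans(tX[, new_rows, drop = FALSE])
      new_cols <- sort(order(cm, decreasing = TRUE)[seq_len(l0)])
      if (identical(new_rows, rows) && identical(new_cols, cols)) break
      rows <- new_rows; cols <- new_cols
    }
    # Stage 2: score-adaptive refinement of both set sizes from that basin.
    for (it in seq_len(max_iter)) {
      g <- best_rows_for_cols(std_expr, cols)
      s <- best_rows_for_cols(tX, g$rows)
      if (identical(g$rows, rows) && identical(s$rows, cols)) break
      rows <- g$rows; cols <- s$rows
    }
    sc <- las_score(length(rows), length(cols),
                    mean(std_expr[rows, cols]), m, n)
    if (sc > best$score) best <- list(rows = rows, cols = cols, score = sc)
  }
  new_bicluster(std_expr, best$rows, best$cols, best$score, method)
}

new_bicluster <- function(std_expr, rows, cols, score, method) {
  structure(list(
    gene_set = rownames(std_expr)[rows],
    sample_set = colnames(std_expr)[cols],
    avg = mean(std_expr[rows, cols]),
    score = score,
    method = method
  ), class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("LAS bicluster: %d genes x %d samples, avg %.3f z, score %.1f (%s)\n",
              length(x$gene_set), length(x$sample_set), x$avg, x$score, x$method))
  invisible(x)
}

#' Call ECM3 status by LAS biclustering of the ECM panel
#'
#' Samples in the top positive-average bicluster are ECM3-positive; all
#' others negative. The per-sample continuous score is the mean
#' standardized expression over the bicluster's gene set. If no
#' positive-average bicluster is found the call is all-negative with a
#' warning.
#'
#' @param expr genes x samples log2 matrix.
#' @param ecm_panel ECM [gene_panel()].
#' @param n_restarts,seed passed to [las_search()].
#' @param scope `"panel"` (default) runs LAS on the panel submatrix;
#'   `"full"` on the whole standardized matrix.
#' @return list with `status` ([signature_status()] tibble) and `bicluster`.
#' @export
call_ecm3 <- function(expr, ecm_panel, n_restarts = 1000, seed = NULL,
                      scope = c("panel", "full")) {
  scope <- match.arg(scope)
  std <- standardize_expression(expr, if (scope == "panel") ecm_panel else NULL)
  bc <- las_search(std, n_restarts = n_restarts, seed = seed)
  if (bc$avg <= 0) {
    warning("no positive-average bicluster found; all samples called ECM3-negative")
    score <- colMeans(std)
    return(list(status = signature_status(colnames(std), rep(FALSE, ncol(std)),
                                          score, "ECM3"),
                bicluster = bc))
  }
  score <- colMeans(std[bc$gene_set, , drop = FALSE])
  pos <- colnames(std) %in% bc$sample_set
  list(status = signature_status(colnames(std), pos, score, "ECM3"),
       bicluster = bc)
}
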