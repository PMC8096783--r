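# Signature reduction: a multi-step selection that shrinks a large panel to
# a parsimonious logistic classifier reproducing the original signature
# status. Stages: direction-filtered Kruskal-Wallis screen -> Spearman-CI
# redundancy pruning -> Bonferroni selection -> all-subset logistic
# regression -> optimal concordance cutoff -> kappa agreement report.
# Stage containment holds throughout: final genes are a subset of the
# survivors of every earlier stage.

#' Kruskal--Wallis screen with direction filtering
#'
#' A panel gene passes when its two-group KW test is significant at `alpha`
#' AND the sign of (median in positives - median in negatives) matches the
#' panel's expected modulation direction.
#'
#' @param expr genes x samples log2 matrix.
#' @param panel [gene_panel()].
#' @param status [signature_status()] tibble (both classes nonempty).
#' @param alpha significance level (default 0.05).
#' @return tibble: `gene`, `direction`, `H`, `p`, `median_diff`, `pass`.
#' @export
kw_screen <- function(expr, panel, status, alpha = 0.05) {
  status <- status[match(colnames(expr), status$sample_id), ]
  pos <- is_positive(status)
  if (all(pos) || all(!pos)) stop("both status classes must be nonempty")
  genes <- intersect(panel$gene, rownames(expr))
  res <- lapply(genes, function(g) {
    v <- expr[g, ]
    kt <- kruskal_wallis(v, pos)
    md <- median(v[pos]) - median(v[!pos])
    dir <- panel$direction[panel$gene == g]
    tibble::tibble(gene = g, direction = dir, H = kt$H, p = kt$p_value,
                   median_diff = md,
                   pass = kt$p_value < alpha & sign(md) == dir)
  })
  do.call(rbind, res)
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' The interval is computed on the rank scale via the Fisher z transform
#' with standard error 1/sqrt(n - 3). A pair is flagged "strong" when the
#' lower confidence limit exceeds 0.6.
#'
#' @param x,y numeric vectors, n >= 4, finite, non-constant.
#' @param confidence confidence level (default 0.95).
#' @return list: `r_s`, `ci_low`, `ci_high`, `n`, `strong`.
#' @export
spearman_ci <- function(x, y, confidence = 0.95) {
  if (length(x) != length(y) || length(x) < 4) stop("need paired vectors, n >= 4")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("correlation undefined for a constant vector")
  }
  r <- cor(x, y, method = "spearman")
  zq <- qnorm(1 - (1 - confidence) / 2)
  if (abs(r) >= 1) {
    lo <- hi <- r
  } else {
    z <- atanh(r)
    se <- 1 / sqrt(length(x) - 3)
    lo <- tanh(z - zq * se); hi <- tanh(z + zq * se)
  }
  list(r_s = r, ci_low = lo, ci_high = hi, n = length(x), strong = lo > 0.6)
}

#' All strongly-correlated gene pairs within a gene set
#'
#' @param expr genes x samples matrix.
#' @param genes gene ids to test pairwise.
#' @param confidence CI level for [spearman_ci()].
#' @return tibble: `gene_i`, `gene_j`, `r_s`, `ci_low`, `ci_high`, `strong`.
#' @export
strong_pairs <- function(expr, genes, confidence = 0.95) {
  if (length(genes) < 2) {
    return(tibble::tibble(gene_i = character(), gene_j = character(),
                          r_s = numeric(), ci_low = numeric(),
                          ci_high = numeric(), strong = logical()))
  }
  pairs <- combn(sort(genes), 2)
  res <- apply(pairs, 2, function(p) {
    s <- spearman_ci(expr[p[1], ], expr[p[2], ], confidence)
    tibble::tibble(gene_i = p[1], gene_j = p[2], r_s = s$r_s,
                   ci_low = s$ci_low, ci_high = s$ci_high, strong = s$strong)
  })
  do.call(rbind, res)
}

#' Prune redundant genes from strong-correlation pairs
#'
#' Iteratively, the gene appearing in the most remaining strong pairs is
#' retained and every gene strongly paired with it is dropped; ties are
#' broken by the relevance ranking (a total order standing in for prior
#' biological knowledge; default position = input order) and then by
#' lexicographic gene id, so the procedure is deterministic.
#'
#' @param genes candidate gene ids.
#' @param pairs tibble from [strong_pairs()] (only rows with
#'   `strong == TRUE` are used).
#' @param relevance_rank character vector of genes, most relevant first;
#'   genes absent from it rank last.
#' @return list: `retained` genes, `dropped` tibble (`gene`, `reason`).
#' @export
prune_redundant <- function(genes, pairs, relevance_rank = genes) {
  pairs <- pairs[pairs$strong & pairs$gene_i %in% genes & pairs$gene_j %in% genes, ,
                 drop = FALSE]
  rank_of <- function(g) {
    r <- match(g, relevance_rank)
    r[is.na(r)] <- length(relevance_rank) + 1L
    r
  }
  retained <- character(0)
  dropped <- tibble::tibble(gene = character(), reason = character())
  remaining <- genes
  while (nrow(pairs) > 0) {
    counts <- table(c(pairs$gene_i, pairs$gene_j))
    top <- max(counts)
    cand <- sort(names(counts)[counts == top])
    cand <- cand[order(rank_of(cand), cand)]
    keep <- cand[1]
    partners <- unique(c(pairs$gene_j[pairs$gene_i == keep],
                         pairs$gene_i[pairs$gene_j == keep]))
    retained <- c(retained, keep)
    dropped <- rbind(dropped, tibble::tibble(
      gene = partners, reason = paste0("strongly correlated with ", keep)))
    remaining <- setdiff(remaining, c(keep, partners))
    pairs <- pairs[!(pairs$gene_i %in% c(keep, partners) |
                       pairs$gene_j %in% c(keep, partners)), , drop = FALSE]
  }
  list(retained = genes[genes %in% c(retained, remaining)], dropped = dropped)
}

#' Bonferroni selection
#'
#' @param genes gene ids.
#' @param p_values per-gene p-values.
#' @param alpha family-wise level in (0, 1).
#' @param m correction denominator (default: number of genes entering the
#'   stage).
#' @return genes with p < alpha / m.
#' @export
bonferroni_select <- function(genes, p_values, alpha = 0.05, m = length(genes)) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < length(genes)) stop("m must be >= number of genes tested")
  genes[p_values < alpha / m]
}

#' Concordance (c-statistic) of scores against binary status
#'
#' Probability that a randomly chosen positive scores above a randomly
#' chosen negative, with ties counting one half (rank formulation).
#'
#' @param scores numeric scores.
#' @param positive logical status.
#' @return c in [0, 1].
#' @export
concordance_stat <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' All-subset logistic regression
#'
#' For every nonempty gene subset up to `max_size`, fits a logistic
#' regression of status on the z-standardized expression of the subset and
#' records the concordance (c-statistic) of fitted probabilities against
#' status. The best model has the highest c; subsets whose c lies within
#' `parsimony_tol` of the maximum are resolved by parsimony (fewest genes,
#' then enumeration order) — the tolerance defaults to 0.02, roughly the
#' in-sample optimism one spurious covariate buys at cohort sizes around
#' 200, so noise genes do not ride into the model on overfit concordance.
#' Perfect separation is handled by clipping coefficients at +/-15 and
#' flagging the model.
#'
#' @param expr genes x samples log2 matrix.
#' @param candidate_genes candidate ids (<= 20; enumeration is exhaustive).
#' @param status [signature_status()] tibble.
#' @param max_size largest subset size tried (default `min(8, candidates)`).
#' @param parsimony_tol concordance band within which a smaller subset is
#'   preferred (default 0.02).
#' @return list: `subsets` tibble (`genes`, `size`, `concordance`),
#'   `best_genes`, `intercept`, `coefficients`, `concordance`,
#'   `separation_flag`.
#' @export
all_subset_logistic <- function(expr, candidate_genes, status,
                                max_size = min(8L, length(candidate_genes)),
                                parsimony_tol = 0.02) {
  if (length(candidate_genes) > 20) stop("more than 20 candidates: enumeration infeasible")
  if (length(candidate_genes) < 1) stop("no candidate genes")
  status <- status[match(colnames(expr), status$sample_id), ]
  y <- as.integer(is_positive(status))
  if (all(y == 1) || all(y == 0)) stop("both classes required")
  z <- zscore_rows(expr, candidate_genes)

  fits <- list()
  for (size in seq_len(min(max_size, length(candidate_genes)))) {
    subs <- combn(candidate_genes, size, simplify = FALSE)
    for (s in subs) {
      X <- cbind(`(Intercept)` = 1, t(z[s, , drop = FALSE]))
      fit <- suppressWarnings(
        stats::glm.fit(X, y, family = binomial(),
                       control = stats::glm.control(maxit = 50)))
      cf <- coef(fit)
      cf[is.na(cf)] <- 0
      sep <- any(abs(cf) > 15) || !fit$converged
      cf <- pmin(pmax(cf, -15), 15)
      lp <- cf[1] + colSums(cf[-1] * z[s, , drop = FALSE])
      fits[[length(fits) + 1L]] <- list(
        genes = s, size = size, concordance = concordance_stat(lp, y == 1),
        intercept = unname(cf[1]), coefficients = unname(cf[-1]),
        separation = sep)
    }
  }
  conc <- vapply(fits, `[[`, numeric(1), "concordance")
  sizes <- vapply(fits, `[[`, numeric(1), "size")
  near <- which(conc >= max(conc) - parsimony_tol)
  best_i <- near[order(sizes[near], near)][1]
  best <- fits[[best_i]]
  if (best$separation) {
    decif_log("perfect separation in best subset model; coefficients clipped at +/-15")
  }
  list(
    subsets = tibble::tibble(
      genes = vapply(fits, function(f) paste(f$genes, collapse = ","), ""),
      size = as.integer(sizes), concordance = conc),
    best_genes = best$genes,
    intercept = best$intercept,
    coefficients = setNames(best$coefficients, best$genes),
    concordance = best$concordance,
    separation_flag = best$separation
  )
}

#' Optimal dichotomization cutoff for continuous scores
#'
#' Scans the thresholds below the minimum, between every adjacent pair of
#' sorted unique scores (midpoints), and above the maximum, and returns the
#' lowest threshold maximizing the agreement fraction between
#' (score >= cutoff) and the binary status.
#'
#' @param scores numeric, non-constant.
#' @param positive logical status (both classes present).
#' @return list: `cutoff`, `agreement`.
#' @export
optimal_cutoff <- function(scores, positive) {
  if (length(unique(scores)) == 1) stop("constant scores: cutoff undefined")
  if (all(positive) || all(!positive)) stop("both classes required")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  agree <- vapply(cand, function(t) mean((scores >= t) == positive), numeric(1))
  best <- which(agree == max(agree))[1]
  list(cutoff = cand[best], agreement = agree[best])
}

#' Full signature-reduction procedure
#'
#' Composes the five stages (KW screen, strong-pair pruning, Bonferroni
#' selection, all-subset logistic regression, optimal cutoff) and reports
#' the Cohen's kappa agreement between the reduced classifier's calls and
#' the original signature status on the training cohort.
#'
#' @param expr genes x samples log2 matrix.
#' @param panel original [gene_panel()].
#' @param status original [signature_status()] tibble.
#' @param alpha KW screen significance level (default 0.05).
#' @param confidence CI level for the Spearman stage (default 0.95).
#' @param max_size largest logistic subset size (default 8).
#' @param max_candidates cap on the genes entering the all-subset stage
#'   (default 12, keeping the exhaustive enumeration to a few thousand
#'   fits); the cap keeps the lowest-p genes.
#' @param parsimony_tol concordance band for the parsimony tie-break
#'   (default 0.02; see [all_subset_logistic()]).
#' @param relevance_rank total order over genes for pruning tie-breaks;
#'   default ascending KW p-value.
#' @param bonferroni_m correction denominator; default the number of genes
#'   entering the Bonferroni stage.
#' @return list: `signature` ([reduced_signature()]) and `trace` with every
#'   stage's decisions (`kw`, `pairs`, `pruned`, `bonferroni_survivors`,
#'   `subsets`, `agreement`).
#' @export
reduce_signature <- function(expr, panel, status, alpha = 0.05,
                             confidence = 0.95, max_size = 8L,
                             max_candidates = 12L, parsimony_tol = 0.02,
                             relevance_rank = NULL, bonferroni_m = NULL) {
  kw <- kw_screen(expr, panel, status, alpha)
  stage1 <- kw$gene[kw$pass]
  if (length(stage1) < 1) stop("no genes pass the KW screen")
  relevance_rank <- relevance_rank %||% kw$gene[order(kw$p)]

  pairs <- strong_pairs(expr, stage1, confidence)
  pruned <- prune_redundant(stage1, pairs, relevance_rank)

  m <- bonferroni_m %||% length(pruned$retained)
  p_of <- kw$p[match(pruned$retained, kw$gene)]
  survivors <- bonferroni_select(pruned$retained, p_of, alpha, m)
  decif_log("Bonferroni stage: m = %d, %d of %d genes survive",
            m, length(survivors), length(pruned$retained))
  if (length(survivors) < 1) stop("no genes survive Bonferroni selection")
  if (length(survivors) > max_candidates) {
    survivors <- survivors[order(p_of[match(survivors, pruned$retained)])][seq_len(max_candidates)]
    decif_log("capped all-subset candidates at %d by ascending KW p", max_candidates)
  }

  asl <- all_subset_logistic(expr, survivors, status, max_size, parsimony_tol)
  z <- zscore_rows(expr, asl$best_genes)
  lp <- asl$intercept + colSums(asl$coefficients * z)
  status_ord <- status[match(colnames(expr), status$sample_id), ]
  oc <- optimal_cutoff(lp, is_positive(status_ord))

  sig <- reduced_signature(
    name = paste0(attr(panel, "name") %||% "signature", "_reduced"),
    genes = asl$best_genes, intercept = asl$intercept,
    coefficients = asl$coefficients, cutoff = oc$cutoff,
    provenance = sprintf("reduced from %d-gene panel on %d samples",
                         nrow(panel), ncol(expr)))

  calls <- apply_reduced(expr, sig)
  agreement <- cohen_kappa(is_positive(calls), is_positive(status_ord))

  list(signature = sig,
       trace = list(kw = kw, stage1_genes = stage1, pairs = pairs,
                    pruned = pruned, bonferroni_m = m,
                    bonferroni_survivors = survivors,
                    subsets = asl$subsets,
                    separation_flag = asl$separation_flag,
                    cutoff_agreement = oc$agreement,
                    agreement = agreement))
}
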