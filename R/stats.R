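# Agreement and association statistics shared across the pipeline.

#' Landis--Koch qualitative interpretation of a kappa value
#' @param kappa numeric in [-1, 1].
#' @return one of poor, slight, fair, moderate, substantial, almost perfect.
#' @export
landis_koch <- function(kappa) {
  cut(kappa, breaks = c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, 1),
      labels = c("poor", "slight", "fair", "moderate", "substantial",
                 "almost perfect"),
      right = TRUE) |> as.character()
}

#' Cohen's kappa for two binary raters with an asymptotic CI
#'
#' kappa = (p_o - p_e) / (1 - p_e). The confidence interval uses the
#' standard asymptotic variance p_o (1 - p_o) / (n (1 - p_e)^2), truncated
#' to [-1, 1]. Interpreted qualitatively with the Landis--Koch bands.
#'
#' @param a,b equal-length binary label vectors (logical, or coercible to
#'   2-level factors with shared levels).
#' @param confidence confidence level (default 0.95).
#' @return list: `contingency` (2x2 counts), `kappa`, `ci_low`, `ci_high`,
#'   `label`, `n`.
#' @export
cohen_kappa <- function(a, b, confidence = 0.95) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  if (length(a) < 2) stop("need >= 2 paired labels")
  lev <- sort(unique(c(as.character(a), as.character(b))))
  if (length(lev) > 2) stop("cohen_kappa expects binary labels")
  if (length(lev) == 1) lev <- c(lev, paste0("not_", lev))
  fa <- factor(as.character(a), levels = lev)
  fb <- factor(as.character(b), levels = lev)
  tab <- table(fa, fb)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    stop("kappa undefined: both raters constant and identical (p_e = 1)")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  zq <- qnorm(1 - (1 - confidence) / 2)
  list(contingency = tab,
       kappa = kappa,
       ci_low = max(-1, kappa - zq * se),
       ci_high = min(1, kappa + zq * se),
       label = landis_koch(kappa),
       n = n)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value obtained by summing the hypergeometric probabilities
#' of all tables (with the observed margins) no more probable than the
#' observed one.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: a margin is zero")
  }
  fisher.test(tab)$p.value
}

#' Kruskal--Wallis rank test
#'
#' Tie-corrected H with a chi-square p-value on g - 1 degrees of freedom.
#' Identical values across all groups give H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels, >= 2 groups with >= 1 value each.
#' @return list: `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  if (length(unique(values)) == 1) {
    return(list(H = 0, p_value = 1, df = nlevels(groups) - 1))
  }
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' First-principal-component surrogate score for CD3 expression
#'
#' The CD3 complex genes (CD3D, CD3E, CD3G, CD247) are z-standardized and
#' the first principal component over samples is used as a single CD3
#' surrogate, with its sign fixed so the score correlates positively with
#' the mean of the genes.
#'
#' @param expr genes x samples log2 matrix.
#' @param cd3_genes gene ids to combine (>= 2 must be present).
#' @return named per-sample score vector with attribute
#'   `explained_variance` (fraction).
#' @export
cd3_pca_score <- function(expr, cd3_genes = c("CD3D", "CD3E", "CD3G", "CD247")) {
  present <- intersect(cd3_genes, rownames(expr))
  if (length(present) < 2) {
    stop("need >= 2 of the CD3 complex genes present; found: ",
         paste(present, collapse = ", "))
  }
  z <- zscore_rows(expr, present)
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  if (cor(score, colMeans(z)) < 0) score <- -score
  attr(score, "explained_variance") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  score
}

#' Normalize an immune gene to CD45 (PTPRC)
#'
#' Default is the difference on the log2 scale (`expr_gene - expr_cd45`);
#' `mode = "ratio"` returns the linear-scale ratio instead.
#'
#' @param expr genes x samples log2 matrix.
#' @param gene immune gene id.
#' @param cd45_gene CD45 gene id (default `PTPRC`).
#' @param mode `"difference"` (log2) or `"ratio"` (linear).
#' @return named per-sample vector.
#' @export
cd45_normalize <- function(expr, gene, cd45_gene = "PTPRC",
                           mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  miss <- setdiff(c(gene, cd45_gene), rownames(expr))
  if (length(miss) > 0) stop("gene(s) absent: ", paste(miss, collapse = ", "))
  if (mode == "difference") expr[gene, ] - expr[cd45_gene, ]
  else 2^(expr[gene, ] - expr[cd45_gene, ])
}

#' Dichotomize an IHC-style marker (percent scale)
#'
#' `rule = "fixed"` calls high when the value is strictly above the given
#' threshold; `rule = "median"` first sets the threshold to the cohort
#' median. Comparisons are strict in both rules, so an all-tied cohort
#' under the median rule is all-low.
#'
#' @param values percentages in [0, 100].
#' @param threshold percent; required for the fixed rule.
#' @param rule `"fixed"` or `"median"`.
#' @return factor with levels `low`, `high`.
#' @export
dichotomize_marker <- function(values, threshold = NULL,
                               rule = c("fixed", "median")) {
  rule <- match.arg(rule)
  if (length(values) == 0) stop("empty marker values")
  if (any(values < 0 | values > 100)) stop("marker values must lie in [0, 100]")
  if (rule == "median") threshold <- median(values)
  if (is.null(threshold)) stop("fixed rule needs a threshold")
  if (threshold < 0 || threshold > 100) stop("threshold must lie in [0, 100]")
  factor(ifelse(values > threshold, "high", "low"), levels = c("low", "high"))
}
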