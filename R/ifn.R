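# Interferon metagene: mean of direction-signed z-scores over the IFN
# panel, dichotomized at the cohort 50th percentile.

#' Compute the IFN metagene score
#'
#' The metagene is the mean over panel genes of `direction` times the
#' gene's z-standardized expression — the standard metagene construction.
#'
#' @param expr genes x samples log2 matrix.
#' @param ifn_panel IFN [gene_panel()].
#' @return named numeric vector of per-sample scores.
#' @export
metagene_score <- function(expr, ifn_panel) {
  validate_expression(expr)
  present <- intersect(ifn_panel$gene, rownames(expr))
  missing <- setdiff(ifn_panel$gene, present)
  if (nrow(ifn_panel) >= 2 && length(present) < 2) {
    stop("fewer than 2 IFN panel genes present; missing: ",
         paste(missing, collapse = ", "))
  }
  if (length(present) == 0) stop("no IFN panel genes present")
  if (length(present) == 1) {
    warning("single-gene IFN panel: metagene equals that gene's z-score")
  }
  if (length(missing) > 0) {
    decif_log("IFN panel gene(s) absent, skipped: %s", paste(missing, collapse = ", "))
  }
  sub <- expr[present, , drop = FALSE]
  mu <- rowMeans(sub, na.rm = TRUE)
  ctr <- sub - mu
  ctr[is.na(ctr)] <- 0
  s <- apply(ctr, 1, sd)
  s[s < .Machine$double.eps^0.5] <- 1  # constant gene contributes 0
  z <- ctr / s
  dirs <- ifn_panel$direction[match(present, ifn_panel$gene)]
  score <- colMeans(dirs * z)
  if (any(!is.finite(score))) stop("non-finite metagene score")
  score
}

#' Dichotomize IFN metagene scores at the cohort median
#'
#' Scores strictly above the 50th percentile are IFN-positive; scores at or
#' below it (including ties at the median) are IFN-negative, so the
#' positive class is conservative and its fraction never exceeds 50%.
#'
#' @param scores named numeric vector from [metagene_score()].
#' @return [signature_status()] tibble for the IFN signature.
#' @export
dichotomize_ifn <- function(scores) {
  if (length(scores) < 2) stop("need >= 2 samples")
  if (length(unique(scores)) == 1) {
    warning("all IFN scores identical; all samples called IFN-negative")
    return(signature_status(names(scores), rep(FALSE, length(scores)),
                            scores, "IFN"))
  }
  cutoff <- median(scores)
  signature_status(names(scores), scores > cutoff, scores, "IFN")
}
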