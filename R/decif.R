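# The ECM3/IFN joint variable, its dichotomous collapse (dECIF), and the
# application of reduced signatures as logistic classifiers.

decif_levels <- c("ECM3+/IFN-", "ECM3+/IFN+", "ECM3-/IFN-", "ECM3-/IFN+")

#' Combine ECM3 and IFN statuses into the joint and dECIF variables
#'
#' The joint variable has the four categories ECM3+/IFN-, ECM3+/IFN+,
#' ECM3-/IFN-, ECM3-/IFN+; the dichotomous dECIF variable contrasts the
#' high-risk ECM3+/IFN- category against "other".
#'
#' @param ecm3,ifn [signature_status()] tibbles over the same sample set.
#' @return tibble with `sample_id`, `joint` (4-level factor), `dichotomous`
#'   (factor `other` / `ECM3+/IFN-`, with `other` the reference level).
#' @export
assign_decif <- function(ecm3, ifn) {
  only <- c(setdiff(ecm3$sample_id, ifn$sample_id),
            setdiff(ifn$sample_id, ecm3$sample_id))
  if (length(only) > 0) {
    stop("sample(s) present in one status input only: ",
         paste(only, collapse = ", "))
  }
  ifn <- ifn[match(ecm3$sample_id, ifn$sample_id), ]
  joint <- paste0(ifelse(is_positive(ecm3), "ECM3+", "ECM3-"),
                  ifelse(is_positive(ifn), "/IFN+", "/IFN-"))
  tibble::tibble(
    sample_id = ecm3$sample_id,
    joint = factor(joint, levels = decif_levels),
    dichotomous = factor(ifelse(joint == "ECM3+/IFN-", "ECM3+/IFN-", "other"),
                         levels = c("other", "ECM3+/IFN-"))
  )
}

#' Construct a reduced signature
#'
#' A fitted parsimonious classifier: gene subset, logistic coefficients on
#' z-standardized expression, and the dichotomization cutoff on the
#' linear-predictor scale.
#'
#' @param name signature name.
#' @param genes ordered gene ids.
#' @param intercept,coefficients logit units per z; one coefficient per gene.
#' @param cutoff linear-predictor units; scores at or above it are positive.
#' @param provenance free-text training provenance.
#' @return object of class `reduced_signature`.
#' @export
reduced_signature <- function(name, genes, intercept, coefficients, cutoff,
                              provenance = "") {
  if (length(coefficients) != length(genes)) {
    stop("coefficient count must equal gene count")
  }
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  structure(list(name = name, genes = as.character(genes),
                 intercept = as.numeric(intercept),
                 coefficients = setNames(as.numeric(coefficients), genes),
                 cutoff = as.numeric(cutoff), provenance = provenance),
            class = "reduced_signature")
}

#' @export
print.reduced_signature <- function(x, ...) {
  cat(sprintf("Reduced signature '%s': %d genes (%s), cutoff %.3f\n",
              x$name, length(x$genes), paste(x$genes, collapse = ", "), x$cutoff))
  invisible(x)
}

# z-standardize the rows of expr restricted to `genes` within the cohort
zscore_rows <- function(expr, genes) {
  sub <- expr[genes, , drop = FALSE]
  mu <- rowMeans(sub, na.rm = TRUE)
  ctr <- sub - mu
  ctr[is.na(ctr)] <- 0
  s <- apply(ctr, 1, sd)
  if (any(s < .Machine$double.eps^0.5)) {
    stop("constant expression for gene(s): ",
         paste(genes[s < .Machine$double.eps^0.5], collapse = ", "))
  }
  ctr / s
}

#' Apply a reduced signature to an expression matrix
#'
#' Signature genes are z-standardized within the cohort (keeping the
#' coefficients transferable across platforms), the linear predictor
#' `intercept + sum(coef * z)` is computed per sample, and samples scoring
#' at or above the cutoff are called positive.
#'
#' @param expr genes x samples log2 matrix.
#' @param sig [reduced_signature()].
#' @return [signature_status()] tibble.
#' @export
apply_reduced <- function(expr, sig) {
  validate_expression(expr)
  miss <- setdiff(sig$genes, rownames(expr))
  if (length(miss) > 0) {
    stop("signature gene(s) missing from expression: ",
         paste(miss, collapse = ", "))
  }
  z <- zscore_rows(expr, sig$genes)
  score <- sig$intercept + colSums(sig$coefficients * z)
  signature_status(colnames(expr), score >= sig$cutoff, score, sig$name)
}
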