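#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor glm median pnorm prcomp qnorm quantile rexp
#'   rnorm binomial fisher.test kruskal.test predict setNames sd
#' @importFrom utils combn read.delim write.table
NULL

# Internal condition helpers. Validation failures stop(); recoverable data
# issues (collapsed duplicates, dropped rows) are signalled as messages so
# callers and tests can capture them, and are also returned in report fields.

decif_log <- function(...) {
  message("decif: ", sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a per-sample signature status table
#'
#' The common result container for every classifier in the package: one row
#' per sample with a binary call and the continuous score it was derived from.
#'
#' @param sample_id character vector of sample identifiers (unique).
#' @param positive logical vector, `TRUE` for signature-positive samples.
#' @param score numeric continuous score (z units or linear-predictor units).
#' @param signature single string naming the signature.
#' @return A tibble with columns `sample_id`, `status` (factor with levels
#'   `negative`, `positive`), `score`, `signature`.
#' @export
signature_status <- function(sample_id, positive, score, signature) {
  stopifnot(length(sample_id) == length(positive),
            length(sample_id) == length(score))
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in signature status")
  if (any(!is.finite(score))) stop("non-finite signature score")
  tibble::tibble(
    sample_id = as.character(sample_id),
    status = factor(ifelse(positive, "positive", "negative"),
                    levels = c("negative", "positive")),
    score = as.numeric(score),
    signature = signature
  )
}

is_positive <- function(status_tbl) status_tbl$status == "positive"
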