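# qPCR translation layer: triplicate Cq aggregation with replicate QC,
# calibrator-based interplate correction, delta-Cq normalization to a
# housekeeping gene (RPLP1 by default; one cycle = one log2 unit of
# expression), classification with the reduced signatures, and cross-assay
# agreement against array-based calls.

#' Aggregate triplicate Cq wells per (sample, gene)
#'
#' Undetermined wells (`NA`) are excluded. Any replicate deviating more
#' than 0.5 cycles from the replicate median is discarded and flagged as an
#' outlier; the remaining replicates are averaged. Groups with fewer than
#' two valid replicates are flagged; groups with none are marked missing.
#' A blank well carrying a real Cq raises a plate-contamination warning.
#'
#' @param wells well tibble as in [read_qpcr()].
#' @param outlier_cycles deviation tolerance in cycles (default 0.5).
#' @return list: `cq` tibble (`plate_id`, `sample_id`, `gene_id`, `cq`,
#'   `n_used`, `flag`), `calibrator` tibble (`plate_id`, `gene_id`, `cq`).
#' @export
aggregate_cq <- function(wells, outlier_cycles = 0.5) {
  wells <- validate_qpcr(wells)
  bad_blank <- wells$well_type == "blank" & !is.na(wells$cq)
  if (any(bad_blank)) {
    warning("contamination: blank well(s) with a measured Cq on plate(s) ",
            paste(unique(wells$plate_id[bad_blank]), collapse = ", "))
  }
  agg_one <- function(v, tol) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(list(cq = NA_real_, n = 0L, flag = "missing"))
    keep <- abs(v - median(v)) <= tol
    flag <- if (!all(keep)) "outlier_discarded" else ""
    v <- v[keep]
    if (length(v) < 2) flag <- paste0(flag, if (nzchar(flag)) ";", "insufficient_replicates")
    list(cq = mean(v), n = length(v), flag = flag)
  }
  samp <- wells[wells$well_type == "sample", ]
  key <- paste(samp$plate_id, samp$sample_id, samp$gene_id, sep = "\r")
  groups <- split(samp$cq, key)
  meta <- samp[!duplicated(key), c("plate_id", "sample_id", "gene_id")]
  meta <- meta[match(names(groups), paste(meta$plate_id, meta$sample_id,
                                          meta$gene_id, sep = "\r")), ]
  res <- lapply(groups, agg_one, tol = outlier_cycles)
  cq <- tibble::tibble(
    plate_id = meta$plate_id, sample_id = meta$sample_id,
    gene_id = meta$gene_id,
    cq = unname(vapply(res, `[[`, numeric(1), "cq")),
    n_used = unname(vapply(res, `[[`, integer(1), "n")),
    flag = unname(vapply(res, `[[`, character(1), "flag")))

  cal <- wells[wells$well_type == "calibrator", ]
  calibrator <- if (nrow(cal) > 0) {
    ckey <- paste(cal$plate_id, cal$gene_id, sep = "\r")
    cres <- lapply(split(cal$cq, ckey), agg_one, tol = outlier_cycles)
    cmeta <- cal[!duplicated(ckey), c("plate_id", "gene_id")]
    cmeta <- cmeta[match(names(cres), paste(cmeta$plate_id, cmeta$gene_id,
                                            sep = "\r")), ]
    tibble::tibble(plate_id = cmeta$plate_id, gene_id = cmeta$gene_id,
                   cq = unname(vapply(cres, `[[`, numeric(1), "cq")))
  } else {
    tibble::tibble(plate_id = character(), gene_id = character(), cq = numeric())
  }
  list(cq = cq, calibrator = calibrator)
}

#' Delta-Cq normalization to a housekeeping gene
#'
#' First, if calibrator measurements are available, each plate's Cq values
#' are shifted by that plate's mean calibrator deviation from the grand
#' calibrator mean, cancelling interplate offsets. Then per-sample
#' expression is `-(Cq_gene - Cq_housekeeping)`, so one cycle earlier than
#' the housekeeping gene means +1 log2 unit (about 2-fold). Samples whose
#' housekeeping Cq is missing are excluded with a log entry.
#'
#' @param agg result of [aggregate_cq()].
#' @param housekeeping_gene housekeeping gene id (default `RPLP1`).
#' @return genes x samples matrix of log2-like expression (housekeeping row
#'   excluded).
#' @export
normalize_dcq <- function(agg, housekeeping_gene = "RPLP1") {
  cq <- agg$cq
  if (nrow(agg$calibrator) > 0) {
    grand <- mean(agg$calibrator$cq, na.rm = TRUE)
    shift <- tapply(agg$calibrator$cq, agg$calibrator$plate_id,
                    function(v) mean(v, na.rm = TRUE) - grand)
    cq$cq <- cq$cq - shift[cq$plate_id]
  }
  hk <- cq[cq$gene_id == housekeeping_gene, ]
  if (nrow(hk) == 0) stop("housekeeping gene '", housekeeping_gene,
                          "' absent from Cq table")
  hk_of <- setNames(hk$cq, hk$sample_id)
  drop <- names(hk_of)[is.na(hk_of)]
  if (length(drop) > 0) {
    decif_log("excluding %d sample(s) with missing housekeeping Cq: %s",
              length(drop), paste(drop, collapse = ", "))
  }
  keep <- cq$gene_id != housekeeping_gene & cq$sample_id %in% hk$sample_id &
    !cq$sample_id %in% drop
  cq <- cq[keep, ]
  genes <- sort(unique(cq$gene_id))
  samples <- unique(cq$sample_id)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(cq$gene_id, cq$sample_id)] <- -(cq$cq - hk_of[cq$sample_id])
  m
}

#' Classify samples from qPCR-derived expression with a reduced signature
#'
#' The delta-Cq expression is z-standardized within the cohort inside
#' [apply_reduced()], so array-trained coefficients transfer to the qPCR
#' scale directly.
#'
#' @param expression genes x samples matrix from [normalize_dcq()].
#' @param sig [reduced_signature()].
#' @return [signature_status()] tibble.
#' @export
classify_from_qpcr <- function(expression, sig) {
  apply_reduced(expression, sig)
}

#' Cross-assay agreement between array-based and qPCR-based calls
#'
#' Cohen's kappa on the matched labels, plus (optionally) a per-gene
#' Spearman correlation with CI between the two platforms' expression.
#'
#' @param status_array,status_qpcr [signature_status()] tibbles (or the
#'   dECIF `dichotomous` columns as factors alongside `sample_id`s).
#' @param expr_array,expr_qpcr optional matched genes x samples matrices
#'   for the per-gene correlation report.
#' @param confidence CI level (default 0.95).
#' @return list: `agreement` ([cohen_kappa()] result), `n_matched`,
#'   `per_gene` tibble (`gene`, `r_s`, `ci_low`, `ci_high`) or `NULL`.
#' @export
cross_assay_agreement <- function(status_array, status_qpcr,
                                  expr_array = NULL, expr_qpcr = NULL,
                                  confidence = 0.95) {
  common <- intersect(status_array$sample_id, status_qpcr$sample_id)
  if (length(common) < 4) stop("fewer than 4 matched samples")
  a <- status_array[match(common, status_array$sample_id), ]
  b <- status_qpcr[match(common, status_qpcr$sample_id), ]
  agreement <- cohen_kappa(is_positive(a), is_positive(b), confidence)
  per_gene <- NULL
  if (!is.null(expr_array) && !is.null(expr_qpcr)) {
    genes <- intersect(rownames(expr_array), rownames(expr_qpcr))
    samples <- intersect(intersect(colnames(expr_array), colnames(expr_qpcr)),
                         common)
    per_gene <- do.call(rbind, lapply(genes, function(g) {
      s <- spearman_ci(expr_array[g, samples], expr_qpcr[g, samples], confidence)
      tibble::tibble(gene = g, r_s = s$r_s, ci_low = s$ci_low,
                     ci_high = s$ci_high)
    }))
  }
  list(agreement = agreement, n_matched = length(common), per_gene = per_gene)
}
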