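# Synthetic-cohort generator. Emulates the statistical structure the
# analysis assumes: a planted sample x gene over-expression bicluster on the
# ECM panel, a correlated latent interferon factor on the IFN panel,
# survival times with group-specific hazards, and triplicate Cq plates
# derived from expression. Every generator is seed-deterministic and
# returns the planted truth so downstream stages can be scored.

#' Simulate a log2 expression cohort with a planted ECM3 bicluster and a
#' latent IFN factor
#'
#' Background values are i.i.d. Normal(0, `noise_sd`) in log2 units. Samples
#' designated ECM3-positive receive a `direction * delta` shift on the
#' bicluster genes. A latent factor f_s ~ Normal(0,1) adds
#' `direction * loading * f_s` to each IFN-panel gene; IFN ground truth is
#' f_s above its own median.
#'
#' @param n_samples number of samples (>= 10).
#' @param ecm_panel,ifn_panel disjoint [gene_panel()]s.
#' @param ecm3_fraction fraction of ECM3-positive samples (default 0.35,
#'   within the 30--40% prevalence reported for this subgroup).
#' @param delta planted log2 over-expression shift (> 0; default 1.5).
#' @param bicluster_genes subset of `ecm_panel$gene` carrying the shift
#'   (default: the whole ECM panel).
#' @param ifn_loadings per-gene loadings on the latent factor (default 1).
#' @param n_noise_genes extra background-only genes appended to the matrix.
#' @param noise_sd background standard deviation in log2 units (default 1).
#' @param seed integer seed.
#' @return list with `expr` (genes x samples matrix) and `truth` (planted
#'   memberships, loadings, latent factor, parameters).
#' @export
simulate_expression <- function(n_samples, ecm_panel, ifn_panel,
                                ecm3_fraction = 0.35, delta = 1.5,
                                bicluster_genes = NULL,
                                ifn_loadings = NULL,
                                n_noise_genes = 0, noise_sd = 1,
                                seed = 1L) {
  if (n_samples < 10) stop("n_samples must be >= 10")
  if (length(intersect(ecm_panel$gene, ifn_panel$gene)) > 0) {
    stop("ECM and IFN panels must be disjoint")
  }
  if (delta <= 0) stop("delta must be > 0")
  bicluster_genes <- bicluster_genes %||% ecm_panel$gene
  if (!all(bicluster_genes %in% ecm_panel$gene)) {
    stop("bicluster_genes must be a subset of the ECM panel")
  }
  ifn_loadings <- ifn_loadings %||% rep(1, nrow(ifn_panel))

  set.seed(seed)
  genes <- c(ecm_panel$gene, ifn_panel$gene,
             if (n_noise_genes > 0) sprintf("NOISE%04d", seq_len(n_noise_genes)))
  samples <- sprintf("S%04d", seq_len(n_samples))
  expr <- matrix(rnorm(length(genes) * n_samples, 0, noise_sd),
                 nrow = length(genes), dimnames = list(genes, samples))

  n_pos <- round(ecm3_fraction * n_samples)
  ecm3_pos <- sample(samples, n_pos)
  dir_ecm <- setNames(ecm_panel$direction, ecm_panel$gene)
  expr[bicluster_genes, ecm3_pos] <- expr[bicluster_genes, ecm3_pos] +
    dir_ecm[bicluster_genes] * delta

  f <- rnorm(n_samples)
  names(f) <- samples
  load_vec <- ifn_loadings * ifn_panel$direction
  expr[ifn_panel$gene, ] <- expr[ifn_panel$gene, ] + outer(load_vec, f)

  truth <- list(
    ecm3_positive_samples = sort(ecm3_pos),
    ifn_positive_samples = sort(samples[f > median(f)]),
    bicluster_genes = bicluster_genes,
    metagene_loadings = setNames(ifn_loadings, ifn_panel$gene),
    latent_factor = f,
    delta = delta, noise_sd = noise_sd, seed = seed
  )
  list(expr = expr, truth = truth)
}

#' Default hazard multipliers for the four ECM3/IFN groups
#'
#' The high-risk ECM3+/IFN- group carries the planted hazard ratio (default
#' 3.2 versus all other groups, matching the headline prognostic contrast);
#' the other three groups share the reference hazard.
#'
#' @param hr_high hazard multiplier for ECM3+/IFN- (default 3.2).
#' @return named numeric vector over the four joint categories.
#' @export
default_hazard_ratios <- function(hr_high = 3.2) {
  c("ECM3+/IFN-" = hr_high, "ECM3+/IFN+" = 1,
    "ECM3-/IFN-" = 1, "ECM3-/IFN+" = 1)
}

#' Simulate overall-survival outcomes with group-specific hazards
#'
#' Event times are exponential with rate `baseline_rate * multiplier`
#' (proportional hazards by construction, so the Cox model downstream is
#' correctly specified); censoring times are independent exponential with
#' rate `censor_rate`.
#'
#' @param labels character vector of group labels, named by sample id (or
#'   unnamed; ids are generated).
#' @param group_hazard_ratios named multiplier per label level (> 0).
#' @param baseline_rate events per month for the reference hazard
#'   (default 0.01).
#' @param censor_rate exponential censoring rate (default 0.008, about 40%
#'   censoring under the default hazards). `Inf` censors everyone at t = 0.
#' @param seed integer seed.
#' @return clinical tibble (`sample_id`, `os_time` months, `os_event`,
#'   `group`).
#' @export
simulate_survival <- function(labels, group_hazard_ratios = default_hazard_ratios(),
                              baseline_rate = 0.01, censor_rate = 0.008,
                              seed = 1L) {
  if (length(labels) == 0) stop("empty label vector")
  if (baseline_rate <= 0 || censor_rate <= 0) stop("rates must be > 0")
  labels <- as.character(labels)
  miss <- setdiff(unique(labels), names(group_hazard_ratios))
  if (length(miss) > 0) stop("no hazard multiplier for label(s): ",
                             paste(miss, collapse = ", "))
  if (any(group_hazard_ratios <= 0)) stop("hazard multipliers must be > 0")
  ids <- names(labels) %||% sprintf("S%04d", seq_along(labels))

  set.seed(seed)
  rate <- baseline_rate * unname(group_hazard_ratios[labels])
  t_event <- rexp(length(labels), rate)
  t_cens <- if (is.infinite(censor_rate)) rep(0, length(labels)) else {
    rexp(length(labels), censor_rate)
  }
  tibble::tibble(
    sample_id = ids,
    os_time = pmin(t_event, t_cens),
    os_event = as.integer(t_event <= t_cens),
    group = labels
  )
}

#' Simulate triplicate qPCR plates from an expression matrix
#'
#' True Cq is `offset - expression` (one log2 unit of expression = one
#' cycle, i.e. amplification efficiency exactly 2). Samples are laid out on
#' plates of `plate_size` in column order; each plate adds its shift to all
#' its wells, including the calibrator wells (true calibrator Cq = `offset`
#' for every gene) that allow interplate correction. Each plate also carries
#' one blank well per gene (undetermined Cq). Replicate noise is
#' Normal(0, `noise_sd_cq`).
#'
#' @param expr genes x samples log2 matrix.
#' @param genes assay genes (must be rows of `expr`).
#' @param housekeeping_gene housekeeping gene id (must be a row of `expr`).
#' @param plate_size samples per plate (default 29, the assay layout).
#' @param noise_sd_cq replicate noise in cycles (default 0).
#' @param plate_shifts per-plate additive shifts in cycles (default all 0).
#' @param offset cycles corresponding to expression 0 (default 25).
#' @param housekeeping_stable emulate an ideally stable housekeeping
#'   transcript (true Cq = `offset` in every sample, the property a
#'   housekeeping gene is selected for); `FALSE` derives it from `expr`
#'   like any other gene (default `TRUE`).
#' @param n_replicates replicates per well group (default 3).
#' @param seed integer seed.
#' @return well tibble as in [read_qpcr()], with attributes `plate_shifts`
#'   and `offset`.
#' @export
simulate_qpcr <- function(expr, genes, housekeeping_gene, plate_size = 29,
                          noise_sd_cq = 0, plate_shifts = NULL, offset = 25,
                          n_replicates = 3, housekeeping_stable = TRUE,
                          seed = 1L) {
  all_genes <- union(genes, housekeeping_gene)
  miss <- setdiff(setdiff(all_genes, if (housekeeping_stable) housekeeping_gene),
                  rownames(expr))
  if (length(miss) > 0) stop("gene(s) absent from expression: ",
                             paste(miss, collapse = ", "))
  if (plate_size < 1) stop("plate layout error: plate_size must be >= 1")
  samples <- colnames(expr)
  plate_of <- ceiling(seq_along(samples) / plate_size)
  n_plates <- max(plate_of)
  plate_shifts <- plate_shifts %||% rep(0, n_plates)
  if (length(plate_shifts) != n_plates) {
    stop("plate layout error: need one shift per plate (", n_plates, ")")
  }

  set.seed(seed)
  grid <- expand.grid(sample_id = samples, gene_id = all_genes,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$plate_id <- sprintf("P%02d", plate_of[match(grid$sample_id, samples)])
  hk_rows <- grid$gene_id == housekeeping_gene & housekeeping_stable
  true_expr <- numeric(nrow(grid))
  true_expr[!hk_rows] <- expr[cbind(grid$gene_id[!hk_rows], grid$sample_id[!hk_rows])]
  true_cq <- offset - true_expr
  grid$cq <- true_cq + plate_shifts[plate_of[match(grid$sample_id, samples)]] +
    rnorm(nrow(grid), 0, noise_sd_cq)
  grid$well_type <- "sample"

  cal <- expand.grid(sample_id = "CALIBRATOR", gene_id = all_genes,
                     replicate = seq_len(n_replicates),
                     plate = seq_len(n_plates),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cal$plate_id <- sprintf("P%02d", cal$plate)
  cal$cq <- offset + plate_shifts[cal$plate] + rnorm(nrow(cal), 0, noise_sd_cq)
  cal$well_type <- "calibrator"
  cal$plate <- NULL

  blank <- expand.grid(sample_id = "BLANK", gene_id = all_genes, replicate = 1L,
                       plate = seq_len(n_plates),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  blank$plate_id <- sprintf("P%02d", blank$plate)
  blank$cq <- NA_real_
  blank$well_type <- "blank"
  blank$plate <- NULL

  cols <- c("plate_id", "well_type", "sample_id", "gene_id", "replicate", "cq")
  wells <- tibble::as_tibble(rbind(grid[cols], cal[cols], blank[cols]))
  wells$cq <- pmin(pmax(wells$cq, 1e-6), 40)
  attr(wells, "plate_shifts") <- plate_shifts
  attr(wells, "offset") <- offset
  validate_qpcr(wells)
}
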