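well_row <- function(cq, rep_idx = seq_along(cq), sample = "S1", gene = "G1",
                     plate = "P01", type = "sample") {
  tibble::tibble(plate_id = plate, well_type = type, sample_id = sample,
                 gene_id = gene, replicate = rep_idx, cq = cq)
}

test_that("triplicate aggregation averages and discards 0.5-cycle outliers", {
  agg <- aggregate_cq(well_row(c(25, 25, 25)))
  expect_equal(agg$cq$cq, 25)
  expect_equal(agg$cq$flag, "")

  out <- aggregate_cq(well_row(c(25.0, 25.1, 27.9)))
  expect_equal(out$cq$cq, 25.05, tolerance = 1e-12)
  expect_match(out$cq$flag, "outlier_discarded")
  expect_equal(out$cq$n_used, 2L)

  nd <- aggregate_cq(well_row(c(NA, NA, NA)))
  expect_true(is.na(nd$cq$cq))
  expect_equal(nd$cq$flag, "missing")

  single <- aggregate_cq(well_row(c(24, NA, NA)))
  expect_match(single$cq$flag, "insufficient_replicates")
})

test_that("a blank well with a measured Cq triggers a contamination warning", {
  wells <- rbind(well_row(c(25, 25, 25)),
                 well_row(30, 1, sample = "BLANK", type = "blank"))
  expect_warning(aggregate_cq(wells), "contamination.*P01")
})

test_that("delta-Cq normalization anchors to the housekeeping gene", {
  wells <- rbind(well_row(c(25, 25, 25), gene = "G1"),
                 well_row(c(24, 24, 24), gene = "G2"),
                 well_row(c(25, 25, 25), gene = "RPLP1"))
  ex <- normalize_dcq(aggregate_cq(wells), "RPLP1")
  expect_equal(ex["G1", "S1"], 0)   # same Cq as housekeeping
  expect_equal(ex["G2", "S1"], 1)   # one cycle earlier = +1 log2 unit
  expect_error(normalize_dcq(aggregate_cq(well_row(c(25, 25, 25))), "RPLP1"),
               "housekeeping")
})

test_that("samples with missing housekeeping Cq are excluded with a log entry", {
  wells <- rbind(well_row(c(25, 25, 25), sample = "S1"),
                 well_row(c(25, 25, 25), sample = "S2"),
                 well_row(c(26, 26, 26), sample = "S1", gene = "RPLP1"),
                 well_row(c(NA, NA, NA), sample = "S2", gene = "RPLP1"))
  expect_message(ex <- normalize_dcq(aggregate_cq(wells), "RPLP1"),
                 "S2")
  expect_equal(colnames(ex), "S1")
})

test_that("adding a constant to one plate leaves corrected results unchanged", {
  p <- make_panels()
  sim <- simulate_expression(20, p$ecm, p$ifn, seed = 81)
  genes <- p$ecm$gene[1:3]
  wells <- simulate_qpcr(sim$expr, genes, "RPLP1", plate_size = 10, seed = 4)
  bumped <- wells
  bumped$cq[bumped$plate_id == "P02"] <- bumped$cq[bumped$plate_id == "P02"] + 2
  ex0 <- normalize_dcq(aggregate_cq(wells), "RPLP1")
  ex1 <- normalize_dcq(aggregate_cq(bumped), "RPLP1")
  expect_equal(ex0, ex1, tolerance = 1e-10)
})

test_that("noiseless plates reproduce the array-based dECIF calls exactly", {
  cohort <- make_cohort(n = 60, delta = 2, seed = 83)
  ecm_sig <- reduced_signature("ECM_reduced", cohort$ecm$gene[1:3], 0,
                               c(1, 1, 1), 0.5)
  ifn_sig <- reduced_signature("IFN_reduced", cohort$ifn$gene[1:2], 0,
                               c(1, 1), 0)
  genes <- c(ecm_sig$genes, ifn_sig$genes)
  wells <- simulate_qpcr(cohort$expr, genes, "RPLP1",
                         plate_shifts = c(0.7, -0.2, 0), seed = 6)
  ex <- normalize_dcq(aggregate_cq(wells), "RPLP1")

  arr <- assign_decif(apply_reduced(cohort$expr, ecm_sig),
                      apply_reduced(cohort$expr, ifn_sig))
  qp <- assign_decif(classify_from_qpcr(ex, ecm_sig),
                     classify_from_qpcr(ex, ifn_sig))
  ca <- cross_assay_agreement(
    status_of(arr$sample_id, arr$dichotomous == "ECM3+/IFN-"),
    status_of(qp$sample_id, qp$dichotomous == "ECM3+/IFN-"))
  expect_equal(ca$agreement$kappa, 1)
})

test_that("cross-assay agreement: identity, null, and per-gene consistency", {
  set.seed(85)
  ids <- paste0("S", 1:60)
  a <- status_of(ids, rep(c(TRUE, FALSE), 30))
  expect_equal(cross_assay_agreement(a, a)$agreement$kappa, 1)

  kappas <- vapply(1:20, function(i) {
    b <- status_of(ids, sample(c(TRUE, FALSE), 60, replace = TRUE))
    c2 <- status_of(ids, sample(c(TRUE, FALSE), 60, replace = TRUE))
    cross_assay_agreement(b, c2)$agreement$kappa
  }, numeric(1))
  expect_lt(abs(mean(kappas)), 0.15)

  m1 <- matrix(rnorm(120), 2, 60, dimnames = list(c("G1", "G2"), ids))
  m2 <- m1 + rnorm(120, sd = 0.3)
  ca <- cross_assay_agreement(a, a, m1, m2)
  for (g in c("G1", "G2")) {
    want <- spearman_ci(m1[g, ], m2[g, ])
    expect_equal(ca$per_gene$r_s[ca$per_gene$gene == g], want$r_s)
    expect_equal(ca$per_gene$ci_low[ca$per_gene$gene == g], want$ci_low)
  }
  expect_error(cross_assay_agreement(a[1:3, ], a[1:3, ]), "4 matched")
})

test_that("noisy plates degrade agreement gracefully but stay substantial", {
  ok <- vapply(1:5, function(seed) {
    cohort <- make_cohort(n = 100, delta = 2, seed = 900 + seed)
    sig <- reduced_signature("ECM_reduced", cohort$ecm$gene[1:4], 0,
                             rep(1, 4), 1)
    wells <- simulate_qpcr(cohort$expr, sig$genes, "RPLP1",
                           noise_sd_cq = 0.5, seed = 910 + seed)
    ex <- normalize_dcq(aggregate_cq(wells), "RPLP1")
    arr <- apply_reduced(cohort$expr, sig)
    qp <- classify_from_qpcr(ex, sig)
    cross_assay_agreement(arr, qp)$agreement$kappa >= 0.6
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})
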