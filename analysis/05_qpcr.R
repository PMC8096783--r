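#!/usr/bin/env Rscript
# qPCR translation of the reduced signatures on the training cohort:
# simulate triplicate plates (29 samples per plate, calibrator and blanks,
# interplate shifts), aggregate and delta-Cq-normalize to RPLP1, classify
# with the reduced signatures, and report the cross-assay agreement with
# the array-based dECIF calls, both noiseless and at 0.5-cycle replicate
# noise.

suppressPackageStartupMessages(library(decif))

expr <- read_expression("results/expr_training.tsv")
read_sig <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  reduced_signature(s$name, s$genes, s$intercept, unlist(s$coefficients),
                    s$cutoff, s$provenance)
}
ecm_sig <- read_sig("results/signature_ecm3_reduced.json")
ifn_sig <- read_sig("results/signature_ifn_reduced.json")
assay_genes <- c(ecm_sig$genes, ifn_sig$genes)
cat(sprintf("assay panel: %d genes + RPLP1 housekeeping\n", length(assay_genes)))

arr <- assign_decif(apply_reduced(expr, ecm_sig), apply_reduced(expr, ifn_sig))
as_status <- function(lab) {
  signature_status(lab$sample_id, lab$dichotomous == "ECM3+/IFN-",
                   as.numeric(lab$dichotomous == "ECM3+/IFN-"), "dECIF")
}

for (noise in c(0, 0.5)) {
  wells <- simulate_qpcr(expr, assay_genes, "RPLP1",
                         plate_shifts = c(0.4, -0.6, 0.1, 0, 0.2),
                         noise_sd_cq = noise, seed = 501)
  if (noise == 0) write_qpcr(wells, "results/qpcr_wells_noiseless.tsv")
  ex <- normalize_dcq(aggregate_cq(wells), "RPLP1")
  qp <- assign_decif(classify_from_qpcr(ex, ecm_sig),
                     classify_from_qpcr(ex, ifn_sig))
  ca <- cross_assay_agreement(as_status(arr), as_status(qp),
                              expr[assay_genes, ], ex)
  cat(sprintf("replicate noise %.1f cycles: kappa = %.3f (95%% CI %.3f-%.3f, %s), n = %d\n",
              noise, ca$agreement$kappa, ca$agreement$ci_low,
              ca$agreement$ci_high, ca$agreement$label, ca$n_matched))
  if (noise == 0.5) {
    write.table(ca$per_gene, "results/qpcr_per_gene_spearman.tsv",
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("per-gene cross-platform Spearman r_s: %.2f-%.2f\n",
                min(ca$per_gene$r_s), max(ca$per_gene$r_s)))
  }
}
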