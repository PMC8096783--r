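#!/usr/bin/env Rscript
# Generate the three synthetic cohorts the downstream analyses run on:
# a 97-sample discovery cohort, a 131-sample training cohort for signature
# reduction and qPCR translation, and a 45-sample validation cohort
# (echoing the three clinical series sizes). Each cohort carries a planted
# ECM3 bicluster (35% prevalence, +1.5 log2 shift), a latent IFN factor,
# and its ground truth, written alongside the expression/clinical tables.

suppressPackageStartupMessages(library(decif))
dir.create("results", showWarnings = FALSE)

ecm_panel <- gene_panel(sprintf("ECM%03d", 1:40), name = "ECM")
ifn_panel <- gene_panel(sprintf("IFN%02d", 1:21), name = "IFN")
write_gene_panel(ecm_panel, "results/panel_ecm.tsv")
write_gene_panel(ifn_panel, "results/panel_ifn.tsv")

cohorts <- list(discovery = list(n = 97, seed = 101),
                training = list(n = 131, seed = 102),
                validation = list(n = 45, seed = 103))

for (nm in names(cohorts)) {
  cfg <- cohorts[[nm]]
  sim <- simulate_expression(cfg$n, ecm_panel, ifn_panel, seed = cfg$seed)
  write_expression(sim$expr, sprintf("results/expr_%s.tsv", nm))
  truth_out <- sim$truth[c("ecm3_positive_samples", "ifn_positive_samples",
                           "bicluster_genes", "latent_factor", "delta",
                           "noise_sd", "seed")]
  truth_out$latent_factor <- as.list(truth_out$latent_factor)
  jsonlite::write_json(
    truth_out,
    sprintf("results/truth_%s.json", nm), auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s cohort: %d samples, %d genes, %d planted ECM3+ (%.0f%%)\n",
              nm, ncol(sim$expr), nrow(sim$expr),
              length(sim$truth$ecm3_positive_samples),
              100 * length(sim$truth$ecm3_positive_samples) / ncol(sim$expr)))
}
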