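#!/usr/bin/env Rscript
# Reduce the ECM and IFN panels to parsimonious logistic classifiers on the
# training cohort: KW screen filtered by modulation direction, Spearman-CI
# redundancy pruning, Bonferroni selection, all-subset logistic regression,
# optimal concordance cutoff. Writes the two reduced signatures (portable
# JSON consumed by 05_qpcr.R) and the kappa agreement against the original
# signature status.

suppressPackageStartupMessages(library(decif))

expr <- read_expression("results/expr_training.tsv")
ecm_panel <- read_gene_panel("results/panel_ecm.tsv", name = "ECM")
ifn_panel <- read_gene_panel("results/panel_ifn.tsv", name = "IFN")

ec <- call_ecm3(expr, ecm_panel, n_restarts = 200, seed = 301)
ifn_st <- dichotomize_ifn(metagene_score(expr, ifn_panel))

for (cfg in list(list(panel = ecm_panel, status = ec$status, tag = "ecm3"),
                 list(panel = ifn_panel, status = ifn_st, tag = "ifn"))) {
  red <- reduce_signature(expr, cfg$panel, cfg$status)
  sig <- red$signature
  tr <- red$trace
  cat(sprintf(
    "%s: %d panel genes -> %d pass KW -> %d after pruning -> %d after Bonferroni -> %d in final model\n",
    cfg$tag, nrow(cfg$panel), length(tr$stage1_genes),
    length(tr$pruned$retained), length(tr$bonferroni_survivors),
    length(sig$genes)))
  cat(sprintf("  final genes: %s\n", paste(sig$genes, collapse = ", ")))
  cat(sprintf("  kappa vs original status: %.3f (95%% CI %.3f-%.3f, %s)\n",
              tr$agreement$kappa, tr$agreement$ci_low, tr$agreement$ci_high,
              tr$agreement$label))
  jsonlite::write_json(
    list(name = sig$name, genes = sig$genes, intercept = sig$intercept,
         coefficients = as.list(sig$coefficients), cutoff = sig$cutoff,
         provenance = sig$provenance),
    sprintf("results/signature_%s_reduced.json", cfg$tag),
    auto_unbox = TRUE, digits = NA)
  write.table(tr$kw, sprintf("results/reduction_%s_kw.tsv", cfg$tag),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
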