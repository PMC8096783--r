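# decif

Classification and prognostic evaluation of high-grade breast cancer by the
joint ECM3/IFN tumor-microenvironment axes, with signature reduction and a
qPCR translation layer.

## The problem

Most biomarkers used to stratify breast cancer are cancer-cell oriented and
ignore the tumor microenvironment. Two transcriptional axes capture
complementary microenvironment biology in bulk expression profiles:

- **ECM3** — a subgroup (roughly a third of breast cancers) with coordinated
  over-expression of structural extracellular-matrix genes, identified as a
  sample bicluster over an ECM gene panel by large-average-submatrix (LAS)
  biclustering;
- **IFN** — a 21-gene interferon-response metagene, dichotomized at the
  cohort median.

Neither axis is strongly prognostic alone, but their joint classification
is: the **dECIF** variable (ECM3⁺/IFN⁻ versus "other") flags a high-risk
subgroup with markedly worse overall survival. This package implements the
full analysis pipeline as tested, reusable code for anyone who wants to
apply, stress-test, or port this classification: LAS biclustering, metagene
scoring, the joint/dichotomous classifier, a signature-reduction procedure
that compresses the panels to a handful of genes, agreement and
immune-association statistics, Kaplan–Meier/log-rank/Cox survival
evaluation, and translation of the reduced classifiers to qPCR ΔCq data.
A synthetic-cohort generator with planted ground truth makes every stage
testable end to end without access to the original cohorts.

## The statistics at the core

A *k* × *ℓ* submatrix of the row-standardized expression matrix with entry
mean τ is scored

S(k, ℓ, τ) = −log Φ(−τ√(kℓ)) − log C(m, k) − log C(n, ℓ),

and the ECM3 cluster is the sample set of the top positive-average
bicluster (stochastic two-stage search with restarts; an exact exhaustive
mode is provided at small scale). The IFN metagene is the mean of
direction-signed z-scores; samples above the cohort 50th percentile are
IFN⁺. Signature reduction runs a direction-filtered Kruskal–Wallis screen,
Spearman-CI redundancy pruning (strong pair = lower 95% confidence limit of
r_s above 0.6), Bonferroni selection, exhaustive all-subset logistic
regression scored by the concordance c-statistic, and an optimal-agreement
cutoff; agreement is reported as Cohen's κ with Landis–Koch interpretation.
Survival contrasts are Cox proportional-hazards fits (Efron ties, Wald CIs)
with the putative better category as reference. qPCR wells are aggregated
from triplicates with a 0.5-cycle outlier rule, calibrator-corrected across
plates, and converted as expression = −ΔCq against the RPLP1 housekeeping
gene (one cycle = one log2 unit).

See `vignettes/decif-methods.Rmd` for the full model description, defaults,
and design choices.

## Worked example

```r
library(decif)

ecm_panel <- gene_panel(sprintf("ECM%03d", 1:40), name = "ECM")
ifn_panel <- gene_panel(sprintf("IFN%02d", 1:21), name = "IFN")
sim <- simulate_expression(97, ecm_panel, ifn_panel, seed = 101)

ec <- call_ecm3(sim$expr, ecm_panel, n_restarts = 200, seed = 201)
ec$bicluster
#> LAS bicluster: 40 genes x 34 samples, avg 0.798 z, score 377.3 (alternating)

ifn <- dichotomize_ifn(metagene_score(sim$expr, ifn_panel))
labels <- assign_decif(ec$status, ifn)
table(labels$joint)
#> ECM3+/IFN- ECM3+/IFN+ ECM3-/IFN- ECM3-/IFN+
#>         15         19         34         29

clin <- simulate_survival(setNames(as.character(labels$joint), labels$sample_id),
                          default_hazard_ratios(3.2), seed = 401)
clin$decif <- factor(ifelse(clin$group == "ECM3+/IFN-", "ECM3+/IFN-", "other"),
                     levels = c("other", "ECM3+/IFN-"))
cox_fit(clin, "decif")[, c("term", "hr", "ci_low", "ci_high", "p_value")]
#>   term               hr ci_low ci_high p_value
#> 1 decifECM3+/IFN-  1.91  0.951    3.85  0.0690

red <- reduce_signature(sim$expr, ecm_panel, ec$status)
red$signature
#> Reduced signature 'ECM_reduced': 2 genes (ECM033, ECM021), cutoff 0.033
red$trace$agreement[c("kappa", "ci_low", "ci_high", "label")]
#> $kappa      0.909
#> $ci_low     0.823
#> $ci_high    0.996
#> $label      "almost perfect"
```

Reading the output: the LAS search recovers the planted 35% ECM3⁺ subgroup
exactly (34/97 samples); 15 samples fall in the high-risk ECM3⁺/IFN⁻
category; on a 97-sample cohort the planted hazard ratio of 3.2 is
estimated at 1.91 with a CI crossing 1 — a faithful picture of the limited
power at this cohort size (the estimate concentrates near 3.2 at n = 1000,
as the acceptance script shows); and the reduction compresses the 40-gene
panel to 2 genes whose calls agree with the full-panel status at κ ≈ 0.91
("almost perfect").

## The analysis workflow

Numbered drivers under `analysis/` run the pipeline end to end on synthetic
cohorts and write their tables under `results/`:

1. `01_simulate.R` — three cohorts (97/131/45 samples) with planted truth;
2. `02_classify.R` — ECM3, IFN, joint and dECIF labels, recovery vs truth;
3. `03_reduce.R` — reduced ECM3/IFN signatures with stage-by-stage counts;
4. `04_survival.R` — KM/log-rank/Cox tables for the dECIF contrast;
5. `05_qpcr.R` — simulated triplicate plates, ΔCq translation, cross-assay
   agreement (noiseless and at 0.5-cycle noise).

Run them in order: `Rscript analysis/01_simulate.R`, etc.

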