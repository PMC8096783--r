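Package: decif
Title: ECM3/IFN Joint Classification and Prognostic Evaluation for High-Grade Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the dichotomous ECM3/IFN (dECIF) prognostic workflow for
    high-grade breast cancer transcriptomics: identification of the ECM3 sample
    cluster by large-average-submatrix biclustering over an extracellular-matrix
    gene panel, interferon metagene scoring with median dichotomization, the
    four-level ECM3/IFN joint variable and its dichotomous collapse, a
    signature-reduction procedure (direction-filtered Kruskal-Wallis screen,
    Spearman confidence-interval redundancy pruning, Bonferroni selection,
    all-subset logistic regression with an optimal concordance cutoff),
    agreement statistics (Cohen's kappa with Landis-Koch interpretation),
    Kaplan-Meier, log-rank and Cox survival evaluation, immune-association
    statistics, and a qPCR delta-Cq translation layer. A synthetic-cohort
    generator provides planted biclusters, a latent interferon factor,
    group-specific survival hazards and triplicate Cq plates so that every
    stage is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    e1071,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
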