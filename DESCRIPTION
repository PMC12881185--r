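Package: lrpsig
Title: Ligand-Receptor Pair Signature Scoring for Immune Checkpoint
    Blockade Response
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs and evaluates a ligand-receptor pair-based
    transcriptomic signature (LRPS) that predicts response to immune
    checkpoint blockade from on-treatment bulk tumor expression profiles.
    Ligand-receptor pairs are expanded to gene sets (receptor complexes
    split into subunits) and scored per sample with a single-sample GSEA
    weighted-ECDF running-sum statistic; a cost-sensitive elastic-net
    penalized logistic regression with a prior-probability offset selects
    predictive pairs and yields effect-size weights; the weighted-average
    LRPS is thresholded by Youden's index and stratified into high/low
    odds-ratio groups. Includes ROC/AUC and confusion-matrix evaluation,
    rank tests, Kaplan-Meier/log-rank and Cox proportional-hazards
    validation with the global Schoenfeld test, and a synthetic-cohort
    generator with planted ligand-receptor signal and score-linked
    survival for end-to-end testing without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    survival,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneSetEnrichment, Classification, Survival,
    ImmunoOncology, Software
RoxygenNote: 7.3.3
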