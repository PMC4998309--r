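Package: nodalstage
Title: Lymph-Node Staging Systems and Survival-Based Cutpoint Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes number-based (pN), ratio-based (rN) and log-odds (LODDS)
    lymph-node stages for cancer cohorts, derives category boundaries by
    scanning a continuous nodal score and merging adjacent bins with similar
    survival, builds composite TNM/TRM/TLM stage groups, and compares the
    staging systems with stratified Kaplan-Meier tables, Spearman correlations
    against retrieval counts, and correlated ROC-AUC contrasts. Includes a
    synthetic gastric-cancer cohort simulator with a stage-migration (Will
    Rogers) scenario generator, and self-contained product-limit, log-rank and
    Cox proportional-hazards machinery.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
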