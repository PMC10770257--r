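Package: bomscope
Title: Bone-Metastasis Feature Discovery from Bulk and Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("BoM", "Scope Developers", email = "bomscope@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for discovering bone-metastasis (BoM)
    associated gene programs from bulk and single-cell RNA-seq counts.
    Implements a two-tier negative-binomial Wald differential-expression
    overlap panel, per-subgroup dot-profile statistics, one-vs-rest
    Wilcoxon marker detection, condition-stratified upregulation screens
    with positive-expression-ratio filtering, a five-step ligand-receptor
    candidate screen against a pair database, within-subgroup and
    pan-cancer Pearson correlation validation, and hypergeometric
    over-representation analysis of gene sets. Ships a seeded synthetic
    data generator with a planted-truth ledger so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
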