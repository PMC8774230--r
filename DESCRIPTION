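Package: dbucogs
Title: Consensus Density-Based UMAP Classification and ROC Gene Signatures
    for Renal Tumor Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to distinguish chromophobe renal cell carcinoma (chRCC)
    from renal oncocytoma (RO) in multi-study expression data: probe-to-gene
    collapsing by a specificity/coverage/robustness score, log-scale
    detection, empirical-Bayes location/scale batch correction with PCA
    batch audits, an iterated random-gene-subset UMAP + DBSCAN consensus
    classifier with plurality voting ("density-based UMAP"), moderated-t
    differential expression, percentile-cutpoint ROC signature selection,
    and preranked gene-set enrichment. Includes a synthetic multi-study
    data generator with planted ground truth so the whole pipeline is
    testable without external downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    jsonlite,
    stats,
    utils,
    uwot,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
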