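Package: tmescope
Title: Tumor Microenvironment Deconvolution, Clustering and Prognostic Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterizes the tumor microenvironment (TME) from bulk
    expression data: immune cell-type deconvolution by nu-support-vector
    regression against a marker signature matrix, TME subtyping by
    hierarchical, K-means and subsampled consensus clustering with
    PAC-based model selection, derivation of TME signature gene modules
    (moderated differential expression, gene clustering, random-forest
    importance pruning), a PCA-based per-sample TMEscore with Cox-sign
    weighting, survival stratification by maximally selected rank
    statistics, immunotherapy-response scoring (ROC/AUC, combination with
    tumor mutational burden), and gene-set enrichment (hypergeometric ORA
    and preranked GSEA). A seeded synthetic-cohort generator produces
    expression, clinical and ground-truth tables with the statistical
    structure the pipeline assumes, so every stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    e1071,
    ranger,
    sva
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    limma,
    fgsea,
    pracma,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
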