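Package: anchorsig
Title: Anchor-Gene Expression Signatures for Disease-Progression Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a prognostic gene-expression signature anchored on a
    single gene (e.g. S100A8 in non-muscle invasive bladder cancer): Pearson
    correlation screening against the anchor, hierarchical clustering of
    samples with the uncentered-correlation/average-linkage convention into
    high- and low-anchor clusters, class prediction with five classifiers
    (compound covariate, Bayesian compound covariate, diagonal LDA, nearest
    centroid, linear SVM) under leave-one-out cross-validation with in-fold
    gene selection, and survival analysis of the resulting clusters
    (Kaplan-Meier, log-rank, multivariate Cox). Includes a synthetic-cohort
    generator with a latent two-cluster structure, cluster-dependent
    progression hazards and right-censoring, so the whole pipeline is
    testable without microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    survival,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
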