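Package: thrombotraj
Title: Single-Cell Pseudotime Trajectory Analysis of Thrombocyte Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs the differentiation continuum of zebrafish
    thrombocytes from index-sorted single-cell RNA-seq expression matrices.
    Provides quality control and TPM renormalization with ERCC spike-in
    handling, an ICA-composite pseudotime ordering (four latent factors,
    Ward clustering into developmental states, staged cell ranking) that is
    cross-validated by a one-dimensional Gaussian-process latent variable
    model, marker-gene discovery by one-vs-rest tree-ensemble Gini
    importance, Gaussian-process likelihood-ratio detection of
    pseudotime-dynamic genes with trend-group clustering, two-group
    differential testing with Holm-Sidak correction, and classification of
    ohnolog (whole-genome duplicate) gene pairs from binarized expression.
    Includes a synthetic-data generator with known ground truth emulating
    the statistical structure of index-sorted plate-based single-cell data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
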