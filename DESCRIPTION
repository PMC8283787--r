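Package: tmekit
Title: Tumor-Microenvironment Signature Scoring, Deconvolution and
    Association Statistics for Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for immuno-oncology analysis of bulk expression data:
    TPM conversion, annotation and batch adjustment of count matrices;
    per-sample gene-signature scoring by single-sample GSEA, principal
    components or z-scores; reference-based tumor-microenvironment
    deconvolution (nu-SVR and simplex-constrained least squares) behind a
    registry of published method names; derivation of signature matrices
    from cluster-labelled single-cell data; batch phenotype, survival and
    ROC association statistics with false-discovery-rate control; mutation
    matrix construction from MAF files and mutation-signature association;
    and sparse risk-model construction. Includes deterministic synthetic
    data generators so every stage is testable without external downloads,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    e1071,
    quadprog,
    survival,
    glmnet,
    pROC,
    sva,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
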