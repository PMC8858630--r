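Package: psnpipe
Title: Single-Cell Analysis Pipeline for Pulmonary Part-Solid Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the bespoke computational
    procedures used in single-cell transcriptomic studies of pulmonary
    part-solid nodules: quality-control filtering and log-normalization of
    UMI count matrices, copy-number-based malignant-cell calling from
    genome-ordered smoothed expression, robust non-negative matrix
    factorization meta-program discovery across samples, gene-signature
    scoring against expression-bin-matched background genes, cell-type
    composition statistics (Wilcoxon rank-sum with Benjamini-Hochberg
    adjustment), a random-intercept linear mixed model with Satterthwaite
    degrees of freedom, and a permutation-tested ligand-receptor
    communication score. Includes a synthetic multi-patient cohort
    generator with planted ground truth so every stage is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    lmerTest,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
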