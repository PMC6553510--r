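Package: advcomm
Title: Ligand-Receptor Cross-Talk Analysis for Annotated Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies directed ligand-receptor communication between
    annotated cell types in single-cell RNA-seq count data using
    expression-positivity fractions: the mean interaction number between an
    ordered pair of cell types is the number of (pair, ligand cell,
    receptor cell) triples with both genes detected, divided by the product
    of the two cell-type sizes. Includes cell-level quality-control
    filtering (gene-count and mitochondrial-fraction thresholds),
    log-normalization, matched-control cell-cycle scoring, genotype
    comparison of interaction matrices, a cell-number downsampling
    robustness check, hypergeometric over-representation testing, readers
    and writers for matrix-market triplet counts, dense TSV, ligand-receptor
    pair lists and GMT gene sets, and a seeded negative-binomial simulator
    that plants known expressing fractions and quality-control offender
    cells for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
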