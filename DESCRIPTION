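Package: medipdmr
Title: Window-Based Differential DNA Methylation Analysis for Sperm
    MeDIP-Seq Biomarkers
Version: 0.1.0
Authors@R:
    person("Medip", "Dmr Maintainers", email = "maintainers@medipdmr.example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-implementation of a genome-wide sperm MeDIP-seq
    differential DNA methylation pipeline: the genome is tiled into fixed
    1-kb windows, per-window read counts are compared between case and
    control sample groups with a conditional negative-binomial exact test
    under a common dispersion, significant adjacent windows are merged into
    differential DNA methylation regions (DMRs), and the resulting DMR set
    is characterized (length, CpG density, log-fold change, gene proximity)
    and validated by label permutation, leave-one-out cross-validation and
    PCA nearest-centroid classification of blinded samples.  A synthetic
    data generator provides negative-binomial count matrices with planted
    DMRs so that every stage is testable without sequencing data, and a
    clinical-statistics stage reproduces group summaries and Student's
    t-tests from a bundled semen-analysis table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
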