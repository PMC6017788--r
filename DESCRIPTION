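Package: episynergy
Title: Epistasis-Guided Discovery and Synergy Analysis of Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for proposing drug combinations from
    statistical epistasis in case-control genome-wide association data.
    Provides SNP-level quality control (missingness, minor allele frequency,
    exact Hardy-Weinberg test, windowed LD pruning), exhaustive pairwise
    SNP-SNP interaction scanning with a 4-df genotype likelihood-ratio test
    and a 1-df dosage interaction test, interval-based SNP-to-gene mapping,
    construction of druggable target pairs and predicted drug combinations,
    hypergeometric enrichment against a combination-database background with
    a permutation null, filtration of target pairs by a chromatin co-opening
    gene network, and Chou-Talalay median-effect/combination-index analysis
    of dose-response data. Includes generators for fully synthetic study
    data so every stage is testable without access-restricted genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
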