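Package: poolsel
Title: Evolve-and-Resequence Pool-Seq Analysis of Sexual Selection Experiments
Version: 0.1.0
Authors@R:
    person("poolsel", "developers", email = "poolsel@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for evolve-and-resequence (E&R) experiments with
    pooled whole-population sequencing. Provides SNP-count ingestion and
    filtering (repeat masks, coverage tails, presence filters), ancestral
    diversity statistics (minor allele frequency, coverage-weighted
    heterozygosity, windowed Watterson theta), temporal effective population
    size estimation from paired allele frequencies with pool-seq two-stage
    sampling corrections, per-SNP binomial-GLM allele-frequency-change scans
    with Bonferroni control, significance-peak calling against gene
    annotation, and competitive-fertility proportion statistics. A
    Wright-Fisher forward simulator with two-stage pool-seq sampling supplies
    ground-truth data so every stage is testable without real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
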