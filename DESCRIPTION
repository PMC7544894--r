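Package: duplexplasma
Title: Error-Corrected Targeted cfDNA Sequencing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for targeted sequencing of circulating
    cell-free DNA (cfDNA) with unique molecular identifiers (UMIs).
    Implements UMI-aware consensus deduplication via adjacency grouping,
    a two-step low-frequency variant caller (pileup screening with
    signal-to-noise and read-position filters, then double-strand
    duplex confirmation), panel-of-normals / impact / matched-normal
    filtering, copy-number calling from per-target coverage log-ratios
    with bimodal-versus-trimodal Gaussian mixture null-distribution
    estimation selected by AIC (including ERBB2/HER2 classification),
    cfDNA fragment-length profiling with short-fragment fractions and
    profile deviation scores, and cohort-level statistics (concordance
    categorization, Wilcoxon rank-sum, Pearson correlation). A seeded
    synthetic-data generator emulates UMI-tagged panel reads with spiked
    variants, per-target coverage with amplified genes, and nucleosomal
    fragment-length mixtures so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    Biostrings
Config/testthat/edition: 3
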