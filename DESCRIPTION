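Package: metadnds
Title: Per-Gene and Sliding-Window dN/dS from Metagenomic Read Pileups
Version: 0.1.0
Authors@R: person("Population Genomics Toolkit Contributors", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Estimates within-population selection (pN/pS, reported as dN/dS)
    for microbial populations from short, unlinked environmental metagenome
    reads tiled to reference genomes. Implements competitive fragment
    recruitment under identity and coverage thresholds, per-base quality
    masking, majority-rule consensus calling, Nei-Gojobori-style fractional
    synonymous/non-synonymous site counting, per-gene and sliding-window
    dN/dS with NaN/Inf conventions for zero-polymorphism genes, an NG86
    pairwise surrogate for per-read and homolog comparisons, a seeded
    454-like read and population simulator, placement-randomization coverage
    nulls, and reporting utilities (category summaries, OLS regressions,
    square-root-transformed homolog comparisons, Kyte-Doolittle hydropathy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
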