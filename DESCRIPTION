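Package: peakcooccur
Title: Integrative Analysis of Transcription-Factor Binding, Motif
    Co-Occurrence, Chromatin Accessibility and Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes a transcription factor's binding landscape from
    post-peak-calling data: consensus peaks across replicate ChIP-seq peak
    sets, promoter/genic/intergenic annotation and nearest-TSS gene
    assignment, position-weight-matrix scanning with two-motif
    co-occurrence classification and spacing statistics
    (Kolmogorov-Smirnov comparison), a genome-aware random-shuffle
    permutation null for interval-set overlap, partitioning of bound sites
    into accessible versus closed chromatin regions from ATAC-seq peaks,
    and chi-squared crosstabs of binding or footprint classes against
    differential-expression direction. Includes deterministic
    synthetic-data generators that plant known class counts, motif
    spacing, accessibility and expression structure so each stage's
    recovery can be verified end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
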