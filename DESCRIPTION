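Package: epimeta
Title: Spike-In Normalized m6A Peak Analytics, Metagene Profiling and
    Drug-Response Models for Epitranscriptomic Studies
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis toolkit for m6A RIP-seq and ChIP-seq
    integration studies: spike-in scaling factors and seeded read thinning,
    GTF transcript models with longest-isoform selection, a strand-aware
    metagene coordinate system (5'UTR/CDS/3'UTR plus fixed-width flanks),
    peak annotation to genomic features with peaks-per-gene burdens,
    permutation tests on peak counts, DEG/m6A gene-set intersections,
    TSS- and peak-centered coverage signal matrices, one-phase exponential
    mRNA decay fits (half-life), and Loewe-additivity synergy scoring of
    two-drug dose-response matrices. A seeded synthetic-data module
    generates every input format with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
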