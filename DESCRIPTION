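Package: utrscreen
Title: Scoring FACS-Binned 3'UTR Reporter Screens
Version: 0.1.0
Authors@R:
    person("utrscreen", "developers", email = "utrscreen@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of sort-seq reporter screens that measure the
    post-transcriptional regulatory activity of short 3'UTR sequence elements
    (8mers). Amplicon FASTQ reads from FACS-sorted GFP-intensity bins are
    quality-filtered and counted per sample barcode, normalized to reads per
    million, and summarized as a bin-weighted expression score in [-2, 2] with
    activating/repressive calls. Companion modules quantify steady-state
    mRNA effects as log2(RNA/DNA) ratios, fit first-order decay half-lives
    from actinomycin-D time courses, test motif categories for enrichment
    among calls with two-sided Fisher exact tests, and count conserved motif
    instances in four-species 3'UTR alignments against shuffled controls.
    A synthetic-screen generator with known ground truth (integration events,
    FACS-style percentile gating, multinomial sequencing, amplicon read
    emission) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
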