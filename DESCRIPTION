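Package: relayscreen
Title: Calling and Motif Statistics for Chromatin-Integrated Enhancer Reporter Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide enhancer reporter screens read out by
    FACS-sorted reporter bins over open-chromatin (ATAC) fragments. Reconstructs
    cloned fragments from read pairs, filters duplicates and PCR background
    artifacts, restricts to stage-matched open chromatin, calls enhancer-positive
    sites with replicate consensus and builds a binarized stage-activity matrix.
    Adds a resampling z-score for transcription-factor motif pair co-localization,
    a relative motif enrichment score across peak sets, plain fold-threshold
    differential accessibility on log2(CPM+1) window counts, and enhancer-to-gene
    assignment from chromatin-interaction anchors with nearest-TSS fallback. A
    synthetic screen generator with full ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
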