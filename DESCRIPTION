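Package: degrontx
Title: Spike-In Normalized Transcriptomics for RNA Polymerase II Degradation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for acute RNA polymerase II (RPB1/RPB2) degron
    experiments: spike-in scale and size factors that stay honest under global
    transcriptional repression, a minimal negative-binomial Wald test for
    differential expression at the 2-fold / FDR < 0.05 convention, coverage-based
    transcription indices (promoter-proximal pausing, post-TES readthrough,
    TT-seq/pSer2 elongation) with strand-aware window arithmetic, metagene
    profiling, 4sU pulse-chase RNA half-life estimation with stable-transcript
    rescaling, and the gene-set classification logic (degradation-upregulated,
    control, length-class, peak-bound genes). Ships a synthetic-data module that
    simulates dual-species count matrices, pulse-chase time courses and coverage
    tracks with recorded ground truth, so the whole pipeline is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
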