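Package: tfcobind
Title: Transcription Factor Co-Binding and Regulatory-Mode Classification
    from ChIP-seq and RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates ChIP-seq peak calls for two transcription factors
    with an RNA-seq count matrix to classify how a stimulus-responsive
    transcriptome is regulated. Implements summit-proximity co-binding
    classification (co-bound / factor-A-only / factor-B-only groups at a
    configurable summit distance), peak-to-gene annotation with an upstream
    padding window, detection of condition-induced binding switches in
    which one factor replaces the other at the same locus, the
    Audic-Claverie exact test for two-library count comparisons with
    Benjamini-Hochberg correction, responsiveness and genotype-dependence
    calling, and the joint Class 1-4 regulatory-mode assignment. A seeded
    synthetic-data generator with a truth manifest supports planted-
    structure recovery tests for every stage, and TSS-centered coverage
    profiles and consensus/PWM motif scanning with dinucleotide-preserving
    shuffled backgrounds round out the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
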