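Package: REcountR
Title: PCR-Free Barcode Counting and Sequencer Size-Bias Profiling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Counts restriction-enzyme-liberated, Illumina-adapter-flanked DNA
    barcodes directly from FASTQ reads by mismatch-tolerant prefix matching,
    with no PCR step in the measurement model. Provides pool-level accuracy
    and precision statistics (coefficient of variation, root mean squared
    deviation from a design composition, Pearson correlation across
    measurement methods), re-pooling volume calculations, per-enzyme-group
    on/off-target accounting for orthogonal-enzyme multiplexed digests,
    sequencer size-bias profiling from paired variable-length size standards
    and constant-length normalization barcodes, per-construct quality-score
    summaries, and ATAC-style classification of paired-end insert sizes into
    nucleosomal bins after seeded subsampling to a fixed read depth. A
    synthetic-data module simulates barcode pools with substitution error,
    per-template PCR amplification bias over cycles, length-dependent
    clustering bias, and paired-end fragment mixtures, so every analysis can
    be exercised and validated without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
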