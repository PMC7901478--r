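Package: uniquant
Title: Proportional Gene-Level Quantification of Prokaryotic RNA-Seq on
    Unique Feature Positions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gene-level counting for prokaryotic RNA-seq from a genome
    alignment. Fragments (reconstructed read pairs) and unpaired reads are
    assigned proportionally to annotated features using only each feature's
    unique (non-overlapping) genomic positions, so that multigene fragments
    arising from operons and overlapping genes are split by overlap length
    instead of being double-counted or discarded. Contributions from
    multimapped records are rescued by an expectation-maximization scheme
    anchored on uniquely mapped counts, and transcripts-per-million values
    are computed on unique positional lengths. Includes a synthetic
    GFF3/SAM fixture generator with an independent per-base counting
    oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
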