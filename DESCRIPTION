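Package: eboxchip
Title: Comparative ChIP-Seq Analysis of bHLH Factors with
    Negative-Binomial Peak Calling and E-Box Motif Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for comparing the genome-wide binding
    of two basic helix-loop-helix (bHLH) transcription factors from
    ChIP-seq tag data.  Implements peak calling against a
    negative-binomial background model with directional tag extension
    and control subtraction, rank-binned peak-overlap matrices,
    specific/shared peak classification by dual P-value cutoffs,
    E-box (CANNTG) scanning with flanking-nucleotide profiling,
    discriminative de novo motif discovery between peak classes,
    genomic-location annotation, and association of peak classes with
    histone-acetylation and DNase-hypersensitivity signal tracks.
    Includes a fully deterministic synthetic-data generator (toy genome,
    planted E-box sites with factor-specific flanking preferences,
    negative-binomial tag background, chromatin-context tracks) so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
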