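Package: annopolish
Title: Coverage-Driven Polishing and Evaluation of Gene Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Repairs common structural errors in transcriptome-assembly gene
    annotations using per-base RNA-Seq read coverage: removes redundant
    transcripts that are proper subsets of other transcripts, splits merged
    gene models at coverage troughs found by exponential-likelihood binary
    segmentation, and trims transcript ends that over-extend into antisense
    neighbours. Also assigns evidence-based confidence classes to genes,
    associates transcripts with tissues or conditions, and evaluates an
    annotation against a reference at the base, exon, intron, transcript and
    gene levels (sensitivity, specificity, F1) together with per-transcript
    annotation edit distances (AED). Includes seeded simulators of genomes,
    annotations and coverage tracks with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
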