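Package: ernatools
Title: Enhancer RNA Identification and Network-Based Functional Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An offline toolkit for calling enhancer RNAs (eRNAs) from a de
    novo assembled transcriptome and annotating their putative functions.
    Transcripts are filtered against protein-coding genes, simple repeats and
    blacklisted regions, gated by coding potential, and intersected with
    enhancer regions built from user-supplied enhancer-marker interval sets
    (overlap or merge combination of center-windowed markers). Downstream,
    eRNAs are quantified from coverage tracks with a coverage-based FPKM,
    wired into Spearman co-expression and peak/loop-based regulatory
    networks with false-discovery-rate control, clustered into dense
    modules by a greedy seed-and-expand algorithm, and annotated by
    hypergeometric gene-set enrichment. A synthetic-fixture generator
    produces every input format the toolkit consumes, so the full pipeline
    runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
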