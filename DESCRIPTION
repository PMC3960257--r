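Package: plastex
Title: Plastid Genome Structure and Transcriptome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of chloroplast (plastid) genomes and their
    transcriptomes at desk scale: detection of the quadripartite genome
    structure (large and small single-copy regions separated by a pair of
    inverted repeats), gene, intron and codon-usage accounting under the
    plastid genetic code, maximal repeat surveys (forward, palindromic and
    reverse orientations) with an expectation-based significance filter,
    an exhaustive mismatch-bounded ungapped read mapper with per-strand
    pileups, FPKM expression profiling, RNA-editing site calling with
    per-site conversion efficiency and codon impact annotation, small-RNA
    footprint discovery from size-stratified coverage, and a fully seeded
    synthetic-data generator so that every stage is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
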