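Package: chloroslip
Title: Transcriptional Slippage and RNA Editing Analysis for Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects simple sequence repeats (SSRs) and the quadripartite
    IR/LSC/SSC structure of circular plastomes, calls C-to-U RNA-editing sites
    and per-SSR transcriptional-slippage frequencies from aligned RNA-seq
    reads, annotates codon-level and frameshift consequences (including
    read-through fusion proteins), compares near-identical plastomes
    (SNV/indel calling, transition/transversion classification, heteroplasmy
    assessment), and ships a synthetic plastome and read simulator with a
    known truth table so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
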