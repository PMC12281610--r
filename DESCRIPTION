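Package: recordseq
Title: Spacer Extraction and Differential Acquisition Analysis for
    CRISPR Transcriptional Recording
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transcriptional recording experiments in
    which an RT-Cas1-Cas2 complex writes RNA-derived spacers into a CRISPR
    array on a recording plasmid. The package simulates recording reads
    with planted ground truth, quality-trims FASTQ input with
    Trimmomatic-style single-end rules, locates direct-repeat-flanked
    spacer cassettes under per-flank mismatch budgets, collapses
    near-identical spacers, places spacers on genome and plasmid
    references with a seeded bounded-Hamming search, counts spacers per
    gene, and tests for differential spacer acquisition between
    environmental conditions with a negative binomial Wald test. A
    companion module selects strongly induced genes from a differential
    expression table and extracts candidate promoter sequences upstream
    of them, strand-aware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    graphics,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
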