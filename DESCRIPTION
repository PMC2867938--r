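Package: extrapol
Title: Discovery and Classification of Extragenic RNA Polymerase II
    Transcription Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for annotating extragenic RNA polymerase
    II (Pol II) transcription sites from ChIP-seq tag data, classifying them
    as transcribed enhancers or promoters/TSSs of non-coding RNA genes from
    their H3K4me1/H3K4me3 chromatin signatures with a linear max-margin
    classifier, and characterising the resulting clusters through CpG-island,
    gene-association, CAGE, Ser5-phosphorylated Pol II, RNA-seq support,
    sequence-conservation and transcription-factor motif-enrichment
    statistics with randomisation-based empirical nulls. Includes a seeded
    synthetic-genome generator that emulates the statistical structure of
    stimulated-macrophage ChIP-seq experiments (broad low enhancer peaks,
    sharp TSS peaks, condition-dependent regulation, promoter-biased CpG
    islands, elevated conservation and planted inflammatory-factor motifs)
    together with a ground-truth table for recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    e1071,
    GenomicRanges,
    IRanges,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
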