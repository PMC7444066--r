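Package: tRFkit
Title: Discovery, Classification and Expression Analysis of tRNA-Derived Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.com", role = c("aut", "cre"))
Description: An end-to-end toolkit for tRNA-derived small RNA (tsRNA/tRF)
    analysis from small RNA-seq: construction of extended mature tRNA
    references (intron removal, CCA addition, 50-nt genomic trailer),
    adapter trimming and hierarchical read annotation (miRNA, then rRNA,
    then tRNA), coordinate-based classification of fragments into the six
    canonical tRF classes with reversible license-plate identifiers,
    expression profiling (length/class distributions, positional coverage,
    reads-per-million normalisation), differential-expression calling on
    count matrices with fold-change and FDR cut-offs, miRNA-style 3'-UTR
    target-site scanning with in-silico site mutagenesis, and qPCR
    2^-ddCt utilities. Includes a synthetic-data generator that emulates a
    small RNA-seq time course so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
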