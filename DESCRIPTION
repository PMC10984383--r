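Package: promptpause
Title: PROMPT Expression, Promoter-Proximal Pausing and Repression Analysis for Nascent Transcription Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of strand-specific nascent transcription data (mNET-seq
    and similar protocols) around gene promoters: quantification of antisense
    promoter upstream transcripts (PROMPTs) in the 500 bp window upstream of
    the TSS, promoter-proximal pause-index statistics, exact Mann-Whitney
    differential testing with zero-count filtering, three-way integration of
    gene-body, PROMPT and pause-index changes, strand-resolved metagene
    profiles from single-nucleotide polymerase positions, RNA G-quadruplex
    coverage scoring (G4Hunter and quadparser), and PWM-based motif enrichment
    between PROMPT groups. Includes a negative-binomial synthetic-data
    generator with planted effect classes so the whole pipeline is testable
    end to end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    Rsamtools,
    BiocGenerics,
    GenomeInfoDb
Config/testthat/edition: 3
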