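Package: umitcr
Title: UMI-Based T Cell Receptor Repertoire Sequencing Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An integrated analysis pipeline for T cell receptor (TCR)
    amplicon libraries that carry ligation-introduced unique molecular
    identifiers (UMIs). The package demultiplexes paired-end Illumina
    read triples into per-sample composite reads, assigns V and J genes
    by tag matching with single-mismatch tolerance and encodes each
    rearrangement as a five-part identifier, performs UMI-based
    correction of both sequence errors and PCR amplification bias,
    reconstructs and translates rearrangements to extract CDR3 regions,
    and summarises repertoires with clone-size spectra, discrete
    power-law maximum-likelihood fits, Gini/Shannon/inverse-Simpson
    diversity indices, fixed-depth subsampling, and annotated-CDR3
    searches. A ground-truthed read simulator reproducing the amplicon
    layout makes every stage testable without sequencer output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    igraph,
    jsonlite,
    Biostrings,
    S4Vectors,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
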