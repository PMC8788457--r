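Package: clashr
Title: Chimeric Read Discovery and RNA-RNA Interaction Analysis for CLASH Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for CLASH (crosslinking, ligation and
    sequencing of hybrids) experiments: preprocessing of raw FASTQ reads
    (adaptor, barcode and UMI trimming; length and quality filtering; read
    collapsing), identification of chimeric reads against two reference sets
    (regulatory RNAs and candidate target RNAs) under three search
    stringencies, scoring of each regulatory/target fragment pair by
    intermolecular RNA duplex free energy with a nearest-neighbor model,
    and aggregation of per-read chimeras into ranked, annotated RNA-RNA
    interactions exported as CSV tables.  A synthetic-library generator
    with a ground-truth manifest supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
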