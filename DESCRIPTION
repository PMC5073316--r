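Package: mitoprofiler
Title: Descriptive Analytics for Annotated Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analytics for circular annotated mitochondrial genomes, built
    around the descriptive repertoire used in insect mitogenomics: per-partition
    nucleotide composition with AT and GC skew, codon usage and relative
    synonymous codon usage (RSCU) under the invertebrate mitochondrial code,
    circular gene-adjacency auditing (overlaps and intergenic spacers),
    start/stop-codon classification including truncated stops, gene-order
    rearrangement detection by circular breakpoint counting, control-region
    element scanning (conserved motifs, homopolymer runs, microsatellites,
    tandem repeats), tRNA stem base-pair auditing, and construction of
    partitioned concatenated protein-coding-gene supermatrices. A synthetic
    annotated-mitogenome generator with a machine-readable truth ledger makes
    every pipeline stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
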