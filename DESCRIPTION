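Package: sporomir
Title: Small RNA Discovery and Temperature-Dependent miRNA Profiling for
    Conifer Embryogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for identifying
    conserved and novel microRNAs in small-RNA sequencing libraries from
    somatic embryos grown at epitype-inducing temperatures (18, 23, 28
    degrees C): read collapsing and length filtering, reference matching
    with isomiR classification, hairpin-based novel miRNA discovery
    (read-stack locus calling, weighted nested-pairing fold, miRNA/miRNA*
    duplex validation), RPKM differential expression with profile
    clustering, plant-style target-site scanning with an expectation
    score, and anti-correlation refinement of miRNA-target pairs
    including epigenetic-regulator classification. A synthetic-data
    module plants MIR hairpin loci, isomiR variants, temperature-
    structured expression and anti-correlated targets into a toy genome
    so that every stage is verifiable by planted-truth recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    generics,
    ggplot2,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
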