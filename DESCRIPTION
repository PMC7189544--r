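Package: eremap
Title: Endogenous Retroelement Expression Atlases and ERE-Derived MHC I
    Peptide Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling endogenous retroelement (ERE) expression
    across tissue panels and for proteogenomic discovery of ERE-derived
    MHC class I-associated peptides (ereMAPs) from matched RNA-seq and
    immunopeptidomic identifications. Implements family-level TPM
    aggregation, tissue median profiles with row Z-scores and
    bootstrap-supported hierarchical clustering, the tau index of tissue
    specificity with max-gap binarization and group enrichment, a
    read-partitioning six-frame-translation proteome builder, target-decoy
    FDR and MHC binding-rank filters, canonical 24-mer arbitration of
    peptide-coding sequences with the 10x rule and an orientation decision
    tree, and downstream peptide analytics: rphm expression profiling,
    methylation correlation, amino-acid composition, and a
    Smith-Waterman/PAM30 viral-homology bootstrap test. A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
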