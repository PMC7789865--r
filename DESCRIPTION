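Package: codonbias
Title: Codon Usage Bias Analysis for Transcriptome Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for synonymous codon usage analysis of
    coding sequences (CDS) from transcriptome assemblies. Implements CDS quality
    filtering, nucleotide and positional GC composition, relative synonymous
    codon usage (RSCU), Wright's effective number of codons (ENc) with its
    GC3s-expected curve, the codon adaptation index (CAI), neutrality
    (GC12 vs GC3) regression, parity-rule-2 bias analysis, correspondence
    analysis of gene-by-codon RSCU matrices, and chi-square identification of
    optimal codons from high- and low-expression gene pools. Includes a
    seeded synthetic CDS generator with known ground truth so every stage of
    the analysis can be validated end to end.
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
    rlang,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
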