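Package: qtloci
Title: Comparative Analysis of Insect-Tolerance QTL Loci Across Cereal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting quantitative trait locus (QTL) marker panels
    onto genome assemblies, inferring homologous chromosomal regions, extracting
    each gene's longest coding isoform, comparing gene content and order across
    genomes (including inversion calling), and homology-based discovery of
    microRNA precursors inside the inferred loci with hairpin secondary-structure
    filtering and miRNA target scoring. Ships a synthetic multi-genome locus
    simulator with full ground truth so every stage is testable without large
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
SystemRequirements: ViennaRNA (RNAfold on PATH) for secondary-structure folding
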