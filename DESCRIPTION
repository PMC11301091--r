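Package: dietshift
Title: Diet-Gene Family Expansion and RNA-Editing Diversification in
    Comparative Insect Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for testing whether diet-related gene families are
    expanded and transcriptionally diversified in a focal predaceous
    species relative to non-predaceous relatives.  Implements ortho-group
    classification from per-species gene-count tables with a cutoff
    robustness sweep, a built-in Pfam diet-domain catalog with Fisher and
    rank-sum enrichment statistics, exonic RPKM expression summaries,
    A-to-I RNA editome characterization from RNA-seq pileups (RNA-DNA
    difference calling, SNP exclusion, bidirectional-region masking,
    strand resolution, recoding annotation, read-backed linkage
    disequilibrium contrast), and a cross-species directional expansion
    test on log2(n+1) gene counts.  A planted-truth simulator generates
    every pipeline input (toy genomes, annotations, repeats, count
    matrices, SNPs, pileups, read co-observations) so each stage can be
    validated against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
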