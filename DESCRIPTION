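Package: lotuscan
Title: Selective-Sweep Scanning and Population Genomics for Domestication
    Resequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative population genomics of domesticated versus
    wild cohorts from multi-sample variant calls: functional annotation of
    variants against gene models (region and codon-level coding effect),
    per-group nucleotide diversity (Tajima's theta-pi) and per-sample
    heterozygosity, Weir-Cockerham FST in sliding windows with Z
    standardization, joint log2 pi-ratio / Z(FST) right-tail sweep scanning
    with region merging and gene assignment, linkage-disequilibrium decay
    curves, neighbor-joining trees with bootstrap support, and Patterson
    -normalized principal component analysis. Includes a Balding-Nichols
    synthetic-cohort generator (divergent groups, implanted sweeps, tunable
    LD, genic reference architecture) that emits consistent FASTA, GFF3, VCF
    and grouping files for end-to-end testing.
License: MIT + file LICENSE
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
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
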