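Package: sweepscan
Title: Selection-Signature Scans and Diversity Analysis for Multi-Breed SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for whole-genome selection-signature
    analysis in structured livestock populations: per-breed heterozygosity,
    PLINK-style runs of homozygosity and the F_ROH inbreeding coefficient,
    identity-by-state and pairwise Weir-Cockerham Fst matrices with
    neighbor-joining trees and genotype PCA, windowed Fst / XP-EHH / LSBL
    sweep scans with empirical right-tail candidate calling and region
    merging, haplotype block / frequency / minimum-spanning-network analysis
    of candidate loci, and gene / SNP-class / peak annotation of candidate
    regions. A Balding-Nichols synthetic-panel generator plants known sweep
    haplotypes and autozygosity tracts so every stage is verifiable against
    ground truth without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ape,
    igraph,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    Biostrings,
    rtracklayer
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
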