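Package: altsweep
Title: Selection Scans and Candidate-Gene Association for High-Altitude
    Adaptation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for detecting selective sweeps
    between a highland and a lowland population group from SNP-array
    genotypes: quality control, LD pruning, identity-by-state
    multidimensional scaling, neighbour-joining trees on pairwise F_ST,
    per-SNP Weir-Cockerham F_ST and cross-population extended haplotype
    homozygosity (XP-EHH) scans, upper-quantile intersection of the two
    statistics with a rescue rule for undefined XP-EHH scores, gene
    annotation of candidate SNPs, and genotype-phenotype association of
    haematological traits with a sex covariate and Fisher's LSD post hoc.
    Includes a Balding-Nichols synthetic-data generator with a mechanical
    sweep model so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
LinkingTo:
    Rcpp
Suggests:
    emmeans,
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
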