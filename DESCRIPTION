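Package: ldhap
Title: Local Haplotype Blocks and Haplotype Variants from Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters single-nucleotide polymorphisms (SNPs) into local
    haplotype blocks from a pairwise linkage-disequilibrium (r-squared) matrix
    using density-based clustering (DBSCAN) with noise removal and optional
    intra-block outlier pruning, identifies per-individual haplotype variants
    as unique SNP-genotype combinations, letter-encodes them with a
    minimum-carrier-frequency filter, and writes the result in six tabular
    interchange layouts ready for haplotype-based genome-wide association and
    genomic-selection tools. Includes a reader for VCF genotypes and
    PLINK-style square r-squared matrices, a dosage-based r-squared routine,
    and a seeded simulator of genotype panels with planted haplotype blocks
    for testing and tutorials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0.0)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    knitr,
    withr
Config/testthat/edition: 3
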