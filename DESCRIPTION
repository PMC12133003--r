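Package: corepanel
Title: Core SNP Panel Selection and Validation for Cultivar Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens a multi-sample genotype call set down to a core panel of
    single-nucleotide polymorphisms (SNPs) sufficient to discriminate crop or
    seaweed cultivars, following a genotyping-by-sequencing workflow: per-call
    depth and biallelic filtering, cultivar consensus genotyping under a gene
    identity threshold, Hardy-Weinberg exact-test and polymorphism screens,
    missingness/minor-allele-frequency/polymorphic-information-content
    filters, and PLINK-style sliding-window linkage-disequilibrium pruning.
    Validates panels by pairwise sample similarity correlation against the
    full marker set, and provides population-structure views (genomic
    relationship matrix PCA, p-distance neighbor-joining trees with
    bootstrap, an EM admixture model with cross-validated selection of the
    number of ancestral populations) plus a Balding-Nichols genotype
    simulator for end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
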