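Package: oxshift
Title: Mitochondrial OXPHOS Remodeling Analysis for Paired Tumor/Benign Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline linking high-resolution respirometry
    coupling and pathway states (SUIT protocols), mitochondrial DNA
    heteroplasmy burden with codon-level consequence annotation against the
    rCRS gene model, delta-delta-Cq mtDNA copy number, and a severe
    respiratory phenotype metagene signature with optimal survival
    cut-point dichotomization (Kaplan-Meier, hazard ratios, Harrell's C).
    Includes seeded synthetic-data generators emulating a paired
    benign/malignant prostate cohort so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    broom,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
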