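Package: pasbarcode
Title: SNP-Barcode Authentication of Patient-Derived Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Authentication of patient-derived xenograft (PDX) samples against a
    reference registry using a 32-SNP TaqMan-style allelic-discrimination barcode.
    Provides a reference-profile registry, a two-channel qPCR signal model with
    genotype calling, integrated multi-locus cross-contamination detection that
    distinguishes true mixtures from inefficient amplification, two-contributor
    mixture-fraction estimation, hierarchical clustering and heatmaps of barcodes,
    random-match and biobank collision probabilities, detection-limit power curves,
    and a seeded synthetic-data generator covering pure profiles, mis-labels,
    two- and three-source mixtures, copy-number allelic imbalance, sex-linked
    dropout, and amplification inefficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
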