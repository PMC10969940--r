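Package: mixupGS
Title: Mixup Data Augmentation for Genomic Prediction with GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genomic prediction toolkit implementing GBLUP with a VanRaden
    genomic relationship matrix, mixup data augmentation restricted to the
    top fraction of training lines, repeated random line-partition
    cross-validation, and NRMSE/MAAPE evaluation on the whole test set and
    on its top-20% subset, comparing conventional versus augmented training.
    Includes a synthetic genotype/phenotype simulator with controlled
    heritability for end-to-end testing without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
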