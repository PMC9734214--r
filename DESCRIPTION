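Package: genebankGP
Title: Genomic Prediction Model Comparison for Structured Genebank Collections
Version: 0.1.0
Authors@R: person("genebankGP", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to compare genomic prediction models for inbred plant
    genetic resources held in genebank collections. Implements genotype
    quality control for SNP dosage panels, population-structure analysis
    (Rogers' distances, principal coordinate analysis, admixture estimation
    with cross-entropy model choice), additive and additive-by-additive
    epistatic genomic relationship kernels, REML-based mixed-model fitting
    for G-BLUP, EG-BLUP, W-BLUP and general plus subpopulation-specific
    additive ridge-regression BLUP (GSA-RRBLUP), mixed-linear-model
    association scans with the simpleM multiple-testing correction, and a
    repeated fivefold cross-validation protocol reporting prediction
    abilities. A synthetic-data module generates admixed inbred panels and
    trait values with known architecture for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    MASS,
    jsonlite,
    optparse,
    VariantAnnotation,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
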