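Package: pgxtl
Title: Transfer Learning of Polygenic Scores for Drug-Response Prediction
    in Two-Arm Pharmacogenomic Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds prognostic and predictive polygenic scores for drug
    response in randomized two-arm pharmacogenomic (PGx) cohorts by
    transfer learning from large disease genome-wide association studies.
    Per-SNP weights pre-trained on disease summary statistics (via
    clumping-and-thresholding or a sparse summary-statistic lasso) are
    fine-tuned on individual-level PGx data with a two-dimensional
    penalized gradient-descent algorithm that jointly updates genotype
    main effects and genotype-by-treatment interaction effects, with
    hyperparameters chosen by nested cross-validation. Includes an
    evaluation suite (variance decomposition, interaction testing,
    treatment-effect stratification) and a spike-and-slab simulator of
    linked disease and drug-response genetic architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
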