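Package: qmapnet
Title: Self-Supervised Unrolled Reconstruction for Accelerated Quantitative MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction toolkit for accelerated quantitative MRI (T1/T2/proton-density
    mapping) from undersampled multi-coil, multi-contrast Cartesian k-space. Implements the
    SENSE-style multi-contrast encoding operator, an unrolled network alternating a residual
    convolutional denoiser with a conjugate-gradient data-consistency solve, and three
    training regimes: supervised, self-supervised via k-space partitioning (SSDU-style), and
    zero-shot self-supervised on a single case with nested train/validation partitions and
    early stopping. Includes gradient checkpointing with a verifiable memory contract,
    a synthetic-data pipeline (parametric tissue phantoms, Biot-Savart loop-coil
    sensitivities, retrospective undersampling), signal models and map fitting for
    multi-echo spin-echo, variable-flip-angle SPGR and qDESS sequences, and NRMSE/SSIM
    evaluation with configurable exclusion rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
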