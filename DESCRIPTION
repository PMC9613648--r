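Package: cellmixup
Title: Mixup, Nonlinear Colour-Space Mixup and WGAN-div Oversampling for
    Imbalanced Cell Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data-augmentation toolkit for severely class-imbalanced
    single-cell image classification. Implements standard mixup with
    constrained interpolation coefficients, a nonlinear mixup that follows
    mixup with a 3D rotation of every pixel in RGB colour space, Wasserstein
    GAN and Wasserstein-divergence GAN critic objectives with a CPU-scale
    adversarial training loop and critic-loss-plateau checkpointing, a
    minority-class-focussed mini-batch sampler that supplements each batch of
    original images with synthetic minority-class images, macro-F1 evaluation
    utilities, and a seeded generator of small single-cell-like imbalanced
    image fixtures so the whole pipeline runs end to end on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
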