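Package: soilspecaug
Title: GAN and EMSA Augmentation of Vis-NIR Soil Spectra for Small-Sample
    Nutrient Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for augmenting small visible/near-infrared (Vis-NIR) soil
    reflectance datasets together with their paired nutrient labels.
    Spectra and one scaled nutrient value per sample are combined into joint
    vectors and augmented two ways: with a least-squares generative
    adversarial network trained on the joint vectors, and with extended
    multiplicative signal augmentation (EMSA), which perturbs per-spectrum
    baseline, multiplicative and polynomial distortion coefficients
    estimated by extended multiplicative signal correction (EMSC).
    Generated checkpoints are scored against real data by first-principal-
    component contribution, score-range diversity and label summary
    statistics; a one-dimensional convolutional network then quantifies how
    many generated samples optimally expand the training set for nutrient
    prediction. A synthetic soil-spectra generator with known
    spectrum-nutrient structure supports end-to-end testing.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
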