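Package: tembo
Title: Elephant Call-Type Classification from Raw Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for classifying elephant vocalizations (roar, rumble,
    trumpet) directly from raw waveforms and from spectrogram features.
    Provides a synthetic call generator for the three acoustically distinct
    call types, an audio preprocessing pipeline (silence trimming, duration
    standardization, stratified splitting), two augmentation regimes (class
    balancing and four-fold expansion via time stretching, pitch shifting and
    additive Gaussian noise), MFCC and chroma constant-Q features, a family of
    raw-waveform convolutional classifiers including a spatial/temporal
    feature-extraction network trained with a built-in autograd engine,
    analytic parameter and FLOP profiling with post-training int8
    quantization, and Gaussian-process Bayesian hyperparameter optimization
    with expected improvement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
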