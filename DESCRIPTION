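Package: miaug
Title: Data Augmentation and CNN Classification for Motor-Imagery EEG Spectrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-class motor-imagery electroencephalography (EEG)
    classification with data augmentation. Continuous C3/Cz/C4 recordings are
    band-pass filtered, epoched, and converted to stacked short-time Fourier
    transform (STFT) spectrogram images; five augmentation strategies
    (geometric transformation, noise addition, autoencoder, variational
    autoencoder, and a deep convolutional generative adversarial network)
    enlarge scarce training sets; generated-image quality is scored with a
    Frechet distance on pluggable feature embeddings; and a compact
    convolutional neural network is evaluated under a stratified 10-fold
    cross-validation protocol with configurable real-to-generated data
    ratios. Includes a synthetic motor-imagery EEG simulator with
    event-related desynchronization/synchronization band-power structure so
    the full pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    grDevices,
    EBImage,
    png,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    dplyr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
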