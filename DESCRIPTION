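Package: flickerprobe
Title: Convolutional Recurrent Models of Flicker Fusion with
    Electrophysiology-Like Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains small convolutional recurrent networks (CRNNs) to
    classify synthetic flicker stimuli as flickering or fused, using a
    published critical-flicker-frequency (CFF) table as the only empirical
    input, and probes the intermediate-layer activity of the trained
    networks for signatures reported in the electrophysiology of flicker:
    stimulus fundamentals and harmonics, frequency-selective resonances,
    near-sinusoidal responses at 10 Hz, and low-frequency envelopes at
    80 Hz. Includes a full synthetic stimulus generator (rectangular
    photic-pulse trains, constants, sinusoidal flicker), minibatch
    assembly around per-condition CFF thresholds, an in-package training
    engine (backpropagation through time with Adam), checkpoint selection
    by raw or Gaussian-smoothed validation loss, and spectral probe tools
    (amplitude spectra, fundamental-frequency profiles, envelope
    extraction by windowed maxima and cubic splines, interval range
    profiles, response-frequency maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
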