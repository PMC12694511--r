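Package: respiq
Title: Respiratory Flow Reconstruction from Near-Field I/Q Impedance Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates near-field mutual-impedance respiratory sensing (a 433 MHz
    transmit/receive dipole pair coupled through the thorax, demodulated to in-phase
    and quadrature channels) and reconstructs the quantitative respiratory flow
    waveform from the sensor output. Provides a physics-based forward simulator with
    subject- and hardware-level non-idealities, the preprocessing pipeline
    (resampling, Butterworth band-passing, derivative features, Yeo-Johnson power
    transformation with robust scaling), a multilayer-perceptron flow regressor with
    Monte-Carlo-dropout reliability scoring under subject-grouped cross-validation,
    breath-cycle feature extraction (onsets, durations, tidal volumes, apnea), and
    agreement evaluation (timing errors, detection rate, Bland-Altman analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    signal,
    car,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
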