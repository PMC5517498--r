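Package: phaselock
Title: Fast EEG Phase Forecasting for Phase-Locked Transcranial
    Alternating Current Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forecasts the dominant frequency and phase of an EEG rhythm a
    short horizon into the future, as required to deliver transcranial
    alternating current stimulation (tACS) phase-locked to ongoing brain
    oscillations. Implements an FFT-based forecaster (elliptic IIR bandpass
    filtering in second-order sections, zero-padded FFT dominant-component
    extraction, filter phase-delay correction, sinusoidal extrapolation), an
    autoregressive Yule-Walker comparator, an offline moving-window
    evaluation harness scored by the phase-locking value (PLV), synthetic
    signal generators (sine-plus-noise and EEG-like drifting-alpha signals),
    parameter-sweep experiments over window sizes and signal-to-noise
    ratios, and diagnostics relating peak-frequency variability and band
    power to phase-locking performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
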