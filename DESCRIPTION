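Package: percort
Title: Perturbational Complexity and Phase-Locking Analysis of Cortical Evoked Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multichannel epidural EEG responses to cortical
    electrical stimulation: preprocessing (re-referencing, band-pass filtering,
    stimulus-artifact interpolation, epoching, baseline-rms trial rejection),
    Morlet time-frequency power with bootstrap significance, spectral-exponent
    estimation, OFF-period (high-frequency suppression) detection, intertrial and
    intersite phase clustering (ITPC/ISPC) with phase-locking duration and
    functional connectivity degree, the state-transition perturbational
    complexity index (PCI-ST) with surrogate SNR calibration, nonparametric group
    statistics with BCa effect sizes, and a seeded synthetic-session generator
    that emulates wakefulness- and anesthesia-like recordings with full ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    boot,
    jsonlite,
    rhdf5,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
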