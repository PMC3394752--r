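Package: somnarch
Title: Sleep-Wake Architecture and EEG Spectral Analysis for Rodent Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Epoch-based analysis of rodent sleep EEG/EMG recordings: per-4-s-epoch
    FFT power spectra on a 0.25 Hz grid with artifact rejection, semi-automatic
    vigilance-state scoring (wake, NREM, REM) from EMG tone and spectral ratios,
    hypnogram architecture metrics (bouts, transitions, state amounts, light/dark
    amplitudes, sleep latency), NREM delta-power normalization and time courses,
    and sleep-deprivation rebound statistics. Includes a seeded synthetic
    polysomnography generator (phase-dependent Markov state dynamics,
    state-specific EEG spectral signatures, a two-process-style homeostatic
    slow-wave process, line archetypes with distinct sleep phenotypes, and a
    6-h forced-wake protocol) so the whole pipeline is testable without animal
    recordings.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
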