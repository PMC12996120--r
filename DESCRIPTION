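Package: phispec
Title: Golden-Ratio Organization of Theta-Alpha EEG Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies whether the ratio of alpha to theta spectral
    centroids in resting-state EEG is organized around the golden ratio
    (phi = 1.618) or the harmonic 2:1 ratio, via the Phi Coupling Index
    (PCI), and relates it to theta-alpha frequency convergence near the
    8 Hz band boundary. Provides the full processing chain (FIR bandpass
    filtering, bad-channel handling, average referencing, epoching with
    amplitude rejection, Welch power spectral densities, 1-Hz binning,
    channel-group averaging, band spectral centroids), an aperiodic (1/f)
    correction with fixed-mode log-log fitting, a validation battery
    (marginal-resampling and band-constrained Monte Carlo null models,
    reference-constant specificity sweep, regularization sensitivity,
    frontal-theta variant, bootstrap correlation inference, partial
    correlation, median-split and subgroup profiles), a synthetic
    resting-EEG and cohort generator for fully offline testing, and a
    small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
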