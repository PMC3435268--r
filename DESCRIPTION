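Package: ecogpac
Title: Phase-Amplitude Coupling of Broadband Power to Cortical Rhythms
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for analysing how broadband (population
    activity) power in cortical surface potentials is entrained on the phase
    of low-frequency rhythms. Implements Hann-window power spectral
    snapshots, Morlet wavelet dynamic spectra, Butterworth/Hilbert analytic
    bands, principal spectral component (PSC) decoupling of broadband from
    rhythmic power, phase-coupling palettes, trial-wise coupling-vector
    statistics, seed-referenced complex phase coherence, signed r-squared
    condition contrasts, and a permutation spatial-overlap statistic.
    Ships a synthetic-data generator emulating a cued finger-movement task
    so every stage is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
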