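Package: emipac
Title: Extended Modulation Index Analysis of Phase-Amplitude Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of phase-amplitude coupling (PAC)
    in single-channel electrophysiological time series (LFP/EEG/ECoG).
    Implements the extended modulation index (eMI): cycle-locked averaging of
    Morlet-wavelet energy maps, jitter/stretch surrogate data, extreme-value
    significance thresholds, and a heuristic that labels each significant
    coupling region as Reliable or Ambiguous depending on whether the
    comodulogram maximum is congruent with a spectral peak. Two reference
    estimators -- the direct PAC estimator (dPAC) and the Kullback-Leibler
    modulation index (MI) -- are provided with a matched surrogate scheme, as
    is a suite of synthetic signal models (coupled oscillatory bursts,
    amplitude modulation, multimodal coupling, no-coupling controls, and
    Gaussian spike trains on a 1/f background) for validating sensitivity,
    specificity and false-positive control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo: Rcpp
Imports:
    Rcpp,
    signal,
    pracma,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
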