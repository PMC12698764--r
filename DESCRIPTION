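Package: eegedge
Title: Low-Channel Wearable EEG Processing: Seizure Detection, Acquisition
    Characterization, and Dual-Device Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desktop toolkit for low-channel (glasses-form-factor) EEG
    processing. Provides a seizure-detection pipeline (zero-phase Butterworth
    filtering, overlapped windowing, a 56-feature-per-channel registry of
    time-domain, spectral, wavelet and entropy descriptors, random-forest
    inference with causal Bayesian-style posterior smoothing, and event-level
    scoring under time-slice cross-validation), the acquisition front-end
    characterization mathematics (input-referred noise, dynamic range,
    noise-free bits, effective number of bits, common-mode rejection ratio,
    and an IFCN guideline compliance check), dual-device agreement analysis
    (DTW-aligned Pearson correlation, Welch periodograms, Bland-Altman), and
    seeded synthetic-EEG generators so every stage is testable without
    external recordings. Reads and writes 16-bit EDF, plain-text seizure
    annotation summaries, and CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
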