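Package: physiowtc
Title: Wavelet Transform Coherence Between Brain and Systemic Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-frequency analysis of coherence between resting-state-network
    BOLD signals and systemic physiological signals (heartbeat interval and
    respiration volume per time). Implements the continuous Morlet wavelet
    transform, cross-wavelet transform and smoothed wavelet transform coherence
    with cone-of-influence handling; Monte-Carlo significance of coherence
    magnitude against autoregressive bootstrap nulls and spectrum-preserving
    phase-shuffled surrogates; phase-offset categorisation of significant
    coherence; a test of temporal variability of coherence against a
    stationary VAR(1) bootstrap null; group-level summaries (percent time with
    significant coherence per frequency band, repeated-measures ANOVA and
    Bonferroni-corrected paired tests); and a synthetic-data generator that
    emulates pulse-oximeter, respiratory-bellows and network-averaged BOLD
    recordings with known ground-truth coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    pracma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
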