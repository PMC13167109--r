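Package: respac
Title: Cortico-Respiratory Phase-Amplitude Coupling in Neonatal EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying coupling between respiration
    and cortical activity in neonatal recordings. Detects breaths and apnoeas
    from impedance pneumography with an adaptive amplitude threshold,
    synchronises EEG and vital-signs streams via shared annotations refined by
    ECG cross-correlation, quantifies phase-amplitude coupling as
    cross-frequency coherence between respiratory phase and narrowband EEG
    amplitude, resolves coupling across the respiratory cycle, estimates
    directionality with a cross-frequency phase-slope index, assesses
    significance against epoch-shuffle surrogates with FDR correction, and
    relates per-recording coupling strength to apnoea rate with a linear
    mixed-effects model. A synthetic-data module generates respiration, EEG
    and dual-device ECG with known ground truth so that every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
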