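Package: teposc
Title: TMS-Evoked EEG Oscillations: Simulation, Time-Frequency Decomposition
    and Cluster Permutation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for oscillatory responses to single-pulse
    transcranial magnetic stimulation (TMS) recorded with EEG. Provides a
    synthetic cohort generator with injectable theta/gamma bursts and
    clinical covariates, Morlet wavelet time-frequency decomposition with
    decibel baseline normalization and temporal binning, frequency-band and
    electrode region-of-interest selection, subject-centered sign-flip and
    group-label cluster-based permutation tests with a maximum-cluster-size
    null distribution, linear mixed-effects modelling of band power, and
    Spearman/FDR symptom-association statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
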