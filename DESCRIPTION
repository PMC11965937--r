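Package: emgfatigue
Title: Muscle-Fatigue Detection from Surface EMG via Ensemble Empirical Mode Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for detecting muscle fatigue during
    isometric contractions from surface electromyography (sEMG). Provides a
    synthetic fatiguing-EMG trial generator with controllable spectral
    compression and amplitude growth; standard sEMG conditioning (band-pass,
    powerline notch, baseline removal); empirical mode decomposition (EMD)
    and its noise-assisted variants (EEMD, CEEMD, CEEMDAN, ICEEMDAN)
    implemented from first principles; windowed extraction of time-domain,
    frequency-domain, time-frequency and nonlinear fatigue features (MAV,
    VAR, RMS, mean/median frequency, instantaneous frequency summaries,
    sample entropy, Hurst exponent); an exact t-SNE embedding to three
    dimensions; and SVM/KNN/ANN classification of perceived-fatigue labels
    with stratified and subject-grouped cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    class,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
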