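Package: datbio
Title: Quantitative EEG Biomarkers for Animal-Assisted Therapy Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the neural effect of dolphin-assisted therapy
    from single-channel frontopolar EEG. Provides a synthetic-EEG cohort
    generator (1/f background plus band-limited brain rhythms), a lossless CSV
    dialect and a minimal single-channel EDF reader/writer, zero-phase
    Butterworth filtering and epoching, Welch power spectral density with
    canonical band decomposition (delta, theta, alpha, beta, gamma),
    event-related-potential averaging, self-affine fluctuation analysis with
    crossover detection and the crossover-similarity statistics S_BA and S_DR,
    a shared-weight one-dimensional convolutional encoder trained with
    contrastive or triplet losses, embedding-distance retrieval, and the
    decibel-scale therapy-efficacy biomarker QB_DAT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
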