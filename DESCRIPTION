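Package: ssarhythm
Title: Adaptive Singular Spectrum Analysis for EEG Rhythm Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts brain rhythms (delta, theta, alpha, beta) from
    single-channel electroencephalography (EEG) recordings by singular
    spectrum analysis (SSA) with a principled embedding-dimension rule
    L = fs/fb that ties the window length to the bandwidth of the rhythm
    of interest. Provides the SSA machinery (time-delay embedding, SVD,
    adaptive grouping by reconstructed-component peak frequency and power,
    diagonal averaging), diagnostics that justify the rule (Toeplitz
    autocovariance spectra, DFT-based eigenvalue approximation, trace
    profiles), a Markov Process Amplitude (MPA) EEG simulator with ocular
    and baseline-drift artifacts for validation, Welch power spectral
    density estimation, reconstruction-error metrics, and alpha-band-power
    classification of eyes-open versus eyes-closed epochs.
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
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
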