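Package: icresponse
Title: Analysis of Inferior Colliculus Multiunit Responses to Tones, Speech, and Noise-Burst Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analyzing multiunit extracellular recordings from the
    auditory midbrain (inferior colliculus): frequency-response-area
    construction and receptive-field property extraction from tone grids,
    peristimulus-time-histogram metrics and driven firing rates over speech
    analysis windows, leave-one-out nearest-neighbor template decoding of
    speech-sound pairs, vector-strength and Rayleigh phase-locking statistics
    for periodic noise-burst trains, and a nonparametric group-comparison
    layer (Kolmogorov-Smirnov screening, Mann-Whitney U, Kruskal-Wallis,
    Brown-Forsythe heteroscedastic ANOVA). Includes an inhomogeneous-Poisson
    synthetic-cohort generator that emulates four experimental groups
    (saline, VPA, VPA+VNS-speech, VPA+VNS-tone) so the full pipeline runs and
    is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
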