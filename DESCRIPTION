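Package: chirpcode
Title: Chirp-Stimulus Analysis of Visually Evoked Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-unit responses to a full-field
    chirp stimulus recorded on multi-electrode arrays (retina or dLGN).
    Builds the 30 s chirp waveform (step, accelerating temporal chirp,
    contrast-ramped 2 Hz chirp), identifies light-responsive units with a
    circular-shift shuffle test on inter-trial PSTH correlations, computes
    response-property indices (quality index, ON-OFF bias, transience,
    latency, response amplitude), fits constrained irradiance (Hill),
    contrast (Naka-Rushton) and temporal-frequency (half-Gaussian) tuning
    curves, and characterises the population visual code with sparse PCA,
    consensus Gaussian-mixture clustering and graph community detection.
    Includes an inhomogeneous-Poisson spike-train generator with known
    ground truth for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mclust,
    igraph,
    jsonlite,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
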