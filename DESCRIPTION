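Package: hdemgid
Title: Task and Effort-Level Identification from High-Density Surface EMG
    Activation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for motion-intention identification from high-density
    surface electromyography (HD-EMG) recorded on multichannel electrode
    grids. Provides channel-quality screening, zero-phase band-pass
    filtering and adaptive least-mean-squares power-line cancellation;
    spatial activation maps on 250 ms windows with interpolation of
    artifact channels; map intensity, center-of-gravity and
    single-differential features; torque-guided epoch selection; iterated
    balanced linear-discriminant evaluation with one-vs-rest performance
    indices; short-term, time-effect and muscle-fatigue evaluation
    protocols; paired-t and mixed repeated-measures ANOVA comparisons with
    Greenhouse-Geisser sphericity handling; and a synthetic HD-EMG session
    simulator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    car,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
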