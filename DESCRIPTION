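Package: popcode
Title: Population Coding and Decoding of Orientation at Perceptual Limits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and maximum-likelihood fitting of a Poisson
    population-coding account of human orientation perception at low
    contrast. Provides Von Mises tuning-curve encoders with Naka-Rushton
    contrast response, maximum a posteriori decoding via resultant
    vectors, the analytic (non-normal) distribution of decoding error
    built from the resultant-length densities of circular random walks,
    rival threshold and two-stage observer models with AICc/BIC
    comparison, two-alternative forced-choice detection threshold
    predictions, posterior-precision and spike-count accounts of
    perceptual confidence, and a synthetic behavioral data generator
    emulating a contrast-varying orientation estimation experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
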