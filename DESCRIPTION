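Package: larvataxis
Title: Diffusion-Based Utility Model of Drosophila Larval Phototaxis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models Drosophila larval light avoidance in the two-choice
    plate assay with a molecular-diffusion utility curve, an error-function
    response of avoidance index to light intensity and exposure time.
    Provides the closed-form diffusion solution, a synthetic plate-assay
    generator with binomial counting noise, a sum-of-squares posterior, a
    Shuffled Complex Evolution Metropolis (SCEM-UA) global optimizer with
    Gelman-Rubin convergence checks, an interval-refining outer loop
    (ISCEM) for parameter estimation, and goodness-of-fit validation
    statistics (error moments, R squared, F test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
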