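Package: dualsource
Title: Modelling Perceptual Decisions from Two Motion Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-alternative motion discrimination experiments in
    which coherent motion is split across two apertures. Provides fixed-step
    n-down/1-up staircase calibration with reversal-based stopping, synthetic
    trial generation from a hierarchical drift-diffusion process, the Wiener
    first-passage-time likelihood with a uniform outlier mixture, hierarchical
    Bayesian drift-diffusion fitting with Gelman-Rubin diagnostics and DIC
    model comparison, an extended two-population attractor (neural-mass)
    simulator with a source-weighting parameter and background-input scaling,
    and the behavioural preprocessing and statistics used around them.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
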