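Package: twophaseprev
Title: Two-Phase Prevalence Estimation with Screening Misclassification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-phase (screen-then-confirm) prevalence surveys of
    autism spectrum disorder and similar conditions. Simulates stratified
    cohorts with known ground truth, applies SCQ-style screening cutoffs,
    models diagnostic-phase participation, and estimates post-stratified
    prevalence with a Bayesian latent-status model that treats observed
    diagnoses as error-prone measurements with known or uncertain sensitivity
    and specificity. Includes deterministic and probabilistic sensitivity
    analyses, high-risk stratum capping, Rogan-Gladen correction, MCMC
    convergence diagnostics, and administrative-prevalence descriptive
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    coda,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
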