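Package: modmedgrowth
Title: Latent-Profile-Moderated Mediation with Latent Growth Curve Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Secondary mechanism analyses for randomised trials in recurrent
    depression: latent profile analysis over mixed continuous/binary baseline
    indicator batteries (EM estimation, BIC selection, relative entropy),
    latent growth curve models for repeated depressive-symptom measurements
    estimated by full-information maximum likelihood with heteroscedastic and
    autocorrelated residual structures, and latent-profile-moderated mediation
    models giving conditional indirect effects, the index of moderated
    mediation, and percentile-bootstrap confidence intervals. Ships a
    calibrated synthetic-trial generator with missing-at-random follow-up so
    the full analytic chain is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
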