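Package: fluxpartnn
Title: Partitioning Eddy-Covariance NEE into GPP and RECO with a
    Physically Constrained Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions half-hourly eddy-covariance net ecosystem exchange
    (NEE) into gross primary production (GPP) and ecosystem respiration
    (RECO) using a two-branch feed-forward neural network whose structure
    encodes the flux sign convention NEE = RECO - GPP, positivity of both
    gross fluxes, a light-use-efficiency product node, and zero GPP in
    darkness. Includes simplified nighttime (Lloyd-Taylor) and daytime
    (rectangular-hyperbola + VPD) reference partitioners, a synthetic
    site-year generator with known GPP/RECO truth, Levenberg-Marquardt
    ensemble training with early stopping, and diagnostic statistics
    (seasonal cycles, diurnal hysteresis, functional-response probes,
    light-use efficiency versus diffuse-radiation proxy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
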