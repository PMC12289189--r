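Package: flightHMM
Title: Hidden Markov Models for Three-Dimensional Flight Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing time-regular three-dimensional animal
    flight tracks with two-state multivariate hidden Markov models.
    Step lengths follow a zero-inflated gamma distribution and yaw and
    pitch turning angles follow wrapped Cauchy distributions; transition
    probabilities depend on covariates (distance to a goal location,
    landmark presence) through a multinomial logit link. Includes
    maximum-likelihood fitting jointly across individuals, Viterbi
    decoding, forward-backward state probabilities, forecast
    pseudo-residual diagnostics, AIC-weight model selection, stationary
    state-probability curves with crossover-distance estimation,
    behavioural search metrics (stops, fly-bys), search-state heat maps,
    and a trajectory simulator with the same statistical structure for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
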