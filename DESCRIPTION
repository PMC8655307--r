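Package: ratstance
Title: Predictive Postural Control Modelling for Standing Rats on Tilting Floors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models quiet bipedal stance of the rat as a stochastic single-link
    inverted pendulum pivoting at the metatarsophalangeal (MTP) joint on a
    tilting floor. Provides a receding-horizon model-predictive controller with
    disturbance preview, sensory-delay compensation and move blocking, plus
    linear and nonlinear proportional-derivative baselines; genetic-algorithm
    identification of the five free model parameters (prediction horizon,
    control horizon, MTP stiffness, MTP viscosity, torque-noise magnitude) from
    centre-of-mass angle traces; sagittal rigid-link marker kinematics with a
    per-segment contribution statistic for the centre-of-mass angle; and a
    synthetic-data generator, parameter-sweep experiments and file/config
    utilities so the whole analysis runs on simulated recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
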