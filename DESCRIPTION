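Package: posselt
Title: Reinforcement-Learning Motor Control of a Muscle-Driven Jaw Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A muscle-driven surrogate of the human masticatory system and a
    Soft Actor-Critic (SAC) controller that learns the neural excitation
    patterns driving the lower mid-incisal point anywhere inside a
    Posselt-style three-dimensional envelope of motion. The jaw surrogate
    couples 24 Hill-type point-to-point actuators in 12 bilateral pairs with
    passive temporomandibular ligament springs, gravity and viscous damping,
    integrated with a semi-implicit Euler scheme. Training maximises a
    three-term reward (log-distance target reaching, muscle-force
    regularization, bilateral symmetry). A performance-analysis platform
    quantifies trained policies by range of motion (convex-hull volume
    fraction), metabolic efficiency, agility, accuracy and symmetry, and
    supports reward-coefficient sweeps with correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
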