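Package: snnbot
Title: Reward-Modulated Spiking Network Controller for Robot Obstacle Avoidance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clock-driven simulator for small spiking neural networks with
    three-factor (reward-modulated) spike-timing-dependent plasticity, an
    adaptive learning-rate rule with weight decay toward baseline, and
    dopaminergic release units that gate learning. Ships the ten-neuron
    obstacle-avoidance controller built from these parts, a deterministic 2D
    environment with a kinematic robot and two ultrasonic range sensors, and
    closed-loop experiment drivers that reproduce single-obstacle learning
    and multi-obstacle course runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
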