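Package: reflexarm
Title: Modular Spinal Reflex Control of a Planar Two-Joint Arm
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Self-contained neuromechanical simulator of human upper-limb
    motor control. A modular spinal-cord network (six reflex pathways with
    tunable synaptic strengths: Ia-MN stretch reflex, reciprocal Ia
    inhibition, heteronymous Ia connections, II static stretch reflex, Ib
    autogenic inhibition and Renshaw recurrent inhibition) integrates
    one-cycle sinusoidal supraspinal commands with delayed muscle-spindle and
    Golgi tendon afferent feedback to drive a planar two-joint arm actuated
    by seven Hill-type muscles. Includes synthetic target-trajectory and EMG
    generators, pathway sweeps, hand-force perturbation experiments,
    configurable gravity magnitude and direction, CMA-ES optimisation of
    supraspinal commands and synaptic strengths, Saltelli/Sobol sensitivity
    analysis, and kinematic, smoothness and EMG-overlap metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
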