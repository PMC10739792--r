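Package: planargait
Title: Muscle-Driven Planar Gait Simulation with Joint Stiffness and
    Coactivation Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-dynamics simulation of a reduced sagittal-plane
    musculoskeletal walker driven by Hill-type muscle-tendon actuators,
    together with the analysis chain built on it: analytic joint stiffness
    from moment arms and series muscle-tendon stiffness, agonist-antagonist
    coactivation indices, imitation-learning reward kernels with activation-
    and stiffness-shaping variants, proximal-policy-optimisation training of
    neural-network gait controllers at desk scale, and slip / uneven-terrain
    survival experiments with chi-squared and ANOVA statistics. A synthetic
    periodic reference gait and EMG-like activation generator stand in for
    motion-capture input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
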