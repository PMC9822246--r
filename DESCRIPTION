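Package: larvaforage
Title: Stochastic Simulation and Trajectory Analysis of Drosophila Larva
    Foraging
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to study how Drosophila larvae explore substrates of
    varying food quality and spatial distribution.  Implements a
    phenomenological crawl/turn/pause agent model of larval locomotion in
    homogeneous and patchy arenas (normal crawling speeds, von Mises
    turning angles, per-second turn and pause probabilities, optional
    distance-dependent inward-turn bias, and area-conserving patch
    fragmentation), together with the matching trajectory-analysis
    pipeline for tracker-style centroid recordings: Kalman smoothing,
    per-frame kinematics, Ramer-Douglas-Peucker turn detection, signed
    turning angles and handedness, inward/outward turn classification,
    and patch-residence metrics.  A synthetic-recording generator with
    full ground truth makes every analysis stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tibble
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
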