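Package: reachsim
Title: Stochastic Optimal Control Simulation of Human Arm Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates goal-directed planar arm reaching under
    signal-dependent motor noise and delayed sensory feedback, and studies
    the joint speed-accuracy and cost-benefit trade-offs that shape movement
    duration, velocity profiles and endpoint dispersion. A two-joint,
    six-muscle arm is driven in closed loop by per-start-point neural
    network controllers whose parameters are optimized with CMA-ES to
    maximize the expected utility of reaching: a temporally discounted
    reward for hitting the target minus the integrated muscular effort and a
    penalty on non-perpendicular hits. The analysis suite computes Fitts'
    law regressions, normalized peak-velocity and movement-time tables, hit
    dispersion histograms with Gaussian fits, and Kullback-Leibler
    divergences between dispersion distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
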