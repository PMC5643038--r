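Package: liftbn
Title: Probabilistic Two-Dimensional Static Model of L5/S1 Spinal Loading
    During Lifting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic two-dimensional static top-down link-segment
    model of sagittal-plane lifting that predicts elbow, shoulder and L5/S1
    reaction moments, erector spinae force, and L5/S1 disc compression and
    shear force from posture, hand load and anthropometry, together with a
    probabilistic layer: seeded Monte Carlo propagation of normally
    distributed joint angles and hand load, a stress-strength interference
    model of disc prolapse (compression versus cadaver-derived compressive
    strength), and exact Bayesian updating of the spinal force distributions
    given Boolean disc-injury evidence by importance weighting, with an
    independent discretized-network verifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
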