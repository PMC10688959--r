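Package: biomechfit
Title: Automated Scaling, Inverse Kinematics and Inverse Dynamics for
    Optical Motion Capture
Version: 0.1.0
Authors@R:
    person("biomechfit", "developers", email = "dev@biomechfit.org",
           role = c("aut", "cre"))
Description: Processes labeled optical motion capture marker trajectories
    and ground reaction force data into subject-specific skeleton scales,
    marker registrations, joint kinematics, segment masses and joint
    torques.  A sequence of linear initializations (functional joint
    centers and axes, analytic center-of-rotation estimates, linear
    center-of-mass and angular dynamics fits) feeds non-convex
    maximum-a-posteriori refinement stages so that residual forces at the
    skeleton root are driven to near zero while retaining a close fit to
    the measured markers.  Includes a minimal articulated rigid-body
    engine (forward kinematics, composite-rigid-body mass matrix,
    Newton-Euler inverse dynamics), readers and writers for TRC and MOT
    files, and a seeded synthetic gait generator that produces
    dynamically consistent marker and force data with known ground truth
    for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
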