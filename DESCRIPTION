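Package: sinkscale
Title: Settling Velocity of Complex Particles by Dynamically Scaled Free-Fall Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the terminal sinking velocity of small, complex-shaped
    biological particles (such as planktonic foraminifera tests) from free-fall
    experiments on enlarged physical models in a viscous working fluid. Implements
    the force-balance drag constraint and Archimedes-number form, the Morrison
    sphere drag correlation, wall-effect corrections for settling in a bounded
    tank, shape-constrained empirical drag-curve fitting, the iterative
    scale-factor planning loop with its convergence criteria, transient settling
    dynamics, two-camera track kinematics with replicate filtering, mesh
    morphometrics (projected area, volume, length) from STL surface meshes, and a
    virtual settling tank that simulates the whole experimental loop for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    splines,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
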