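Package: exoflex
Title: Closed-Loop Musculoskeletal Simulation of Elbow Flexion with a
    Cable-Driven Exosuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained closed-loop co-simulation of a six-muscle planar
    elbow driven by computed muscle control and assisted by a
    gravity-compensation cable exosuit.  Each control step combines inverse
    dynamics with PD feedback on the tracking error, resolves muscle redundancy
    by minimizing summed squared activations, inverts first-order activation
    dynamics to obtain excitations, and integrates Hill-type forward dynamics.
    Reports joint moments, muscle activations, elbow joint reaction forces,
    strap interaction forces, and Umberger-family metabolic cost, with and
    without assistance, over a speed-by-load task sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
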