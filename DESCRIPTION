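Package: canard4d
Title: Slow Manifolds, Canard Orbits and Mixed-Mode Oscillations in
    Four-Dimensional Slow-Fast Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes two-dimensional attracting and saddle slow manifolds,
    their fast stable and unstable manifolds, and canard orbits in
    four-dimensional slow-fast vector fields with two fast and two slow
    variables.  Orbit segments are solved as two-point boundary-value
    problems by piecewise-polynomial collocation with the total time as a
    free parameter, and families are traversed by pseudo-arclength
    continuation with event detection.  Includes singular-limit analysis
    (critical manifolds, fold curves, desingularized reduced systems,
    folded singularities and canard-count predictions), equilibrium and
    periodic-orbit continuation with Hopf, period-doubling and branch-point
    detection, and mixed-mode-oscillation signature extraction.  Ships two
    built-in case studies: an extended folded-node normal form and the
    nondimensionalized four-dimensional Hodgkin-Huxley model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
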