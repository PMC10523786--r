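Package: cavsim
Title: Agent-Based Simulation of Cardiac Allograft Vasculopathy in an
    Idealized Coronary Cross-Section
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic agent-based model of cardiac allograft vasculopathy
    (CAV) in an idealized mouse left-coronary-artery cross-section on a
    hexagonal lattice. Smooth muscle cell, extracellular matrix and
    macrophage dynamics are driven by an inflammatory input and by wall
    shear stress dependent endothelial dysfunction; the package provides
    the full 4-week simulation engine, the scenario suite, calibration of
    the matrix-degradation balance coefficient, lumen asymmetry metrics,
    and Latin hypercube / partial rank correlation global sensitivity
    analysis, with tidy tabular results and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
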