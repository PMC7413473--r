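Package: cathflow
Title: Catheter-Tip Hemodynamics and Platelet Damage Scoring in Two Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale computational assessment of hemodialysis catheter
    side-hole designs. Solves steady laminar incompressible blood flow with
    Carreau shear-thinning rheology on parameterized two-dimensional
    catheter-tip geometries using a staggered-grid finite-volume SIMPLE
    scheme, tracks platelets through the converged field with
    Schiller-Naumann drag and generalized Saffman shear lift, and scores
    each design with tip-volume shear statistics, platelet residence times
    and a power-law platelet lysis index. Includes analytic flow fixtures
    with closed-form shear fields, VTK legacy ASCII field I/O, a
    grid-convergence study and a design-comparison report layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
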