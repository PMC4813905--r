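Package: probeflex
Title: Insertion Mechanics of Polymer-Coated Flexible Neural Probes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and design explorer for the insertion
    mechanics of flexible neural microprobes stiffened by a sacrificial
    polymer coating. Predicts the critical buckling force of coated and
    uncoated probes (composite-section Euler theory and a finite-element
    beam eigensolver), the tissue insertion force (a reduced-dimension
    quasi-static penetration solver with one-term Ogden hyperelasticity,
    shear-strain element deletion, penalty contact and Coulomb friction,
    plus a calibrated analytic surrogate for large sweeps), the
    buckling-to-insertion "safety factor", and the logistic mapping from
    safety factor to empirical insertion probability. Includes design-space
    probability maps with bivariate statistics, multi-variable regression
    of safety factor on design parameters, and coating-defect sensitivity
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    tools,
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
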