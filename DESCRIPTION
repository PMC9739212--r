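Package: qsarfield
Title: Grid-Based 3D-QSAR Modelling with CoMFA/CoMSIA Fields and PLS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds comparative molecular field (CoMFA) and molecular
    similarity index (CoMSIA) descriptors on a lattice around aligned
    small-molecule series, fits them to inhibitory activities (pIC50) with
    a native NIPALS partial-least-squares engine under leave-one-out
    cross-validation, and runs the standard internal/external validation
    battery: q2/PRESS, predictive R2, Golbraikh-Tropsha through-origin
    criteria, rm2, and Y-randomization. StDev*Coeff contour volumes are
    exported in OpenDX format. A synthetic congeneric-series generator
    with a planted field-to-activity linear model makes every stage of
    the pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
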