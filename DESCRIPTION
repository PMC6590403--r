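Package: vfareg
Title: Vector-Field-Analysis Surface Registration for Attributed 3-D Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid registration of 3-D point clouds carrying integer "form
    attribute" labels on anatomical features, as used for automatic patient
    registration in image-guided surgery. Implements attribute-constrained
    (binary) closest-point matching, a Gaussian scale-space registration
    energy, vector-field analysis of the induced force field (gradient, curl,
    vortex detection) to select an instant center of rotation, and
    quasi-Newton minimization with Armijo backtracking. Includes the classic
    Gaussian-fields baseline with soft attribute distances, a synthetic
    skull-like phantom and polar-grid A-mode ultrasound scan generator, and
    evaluation tools: target registration error, color-coded distance maps,
    basin-of-convergence sweeps and energy-surface grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
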