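Package: epdd
Title: Primary-Tail Modelling of Electron-Beam Percent Depth Dose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for empirical modelling of electron-beam percent depth dose
    (PDD) curves in radiotherapy dosimetry. Implements the four-parameter
    primary-tail model of the central-axis depth dose, bounded nonlinear
    least-squares fitting of measured water-phantom scans, extraction of
    clinical beam-quality metrics (d_max, R90, R50, practical range, distal
    falloff slope, bremsstrahlung contamination, mean and most probable
    energy), empirical energy regressions and a stopping-power depth
    correction, and the minimal square-field side length required for lateral
    scatter equilibrium (LSE) when collimating electron fields with cutouts.
    Curves are plain tibbles, fitted models ship broom-style tidiers and
    ggplot2 autoplot methods, and a small command-line interface wraps the
    main operations for scripted beam commissioning workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
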