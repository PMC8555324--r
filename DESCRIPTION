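Package: pbsmatch
Title: Beam-Matching Analysis for Proton Pencil-Beam-Scanning Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying dosimetric agreement between
    beam-matched gantries of a multiroom proton pencil-beam-scanning system.
    Models integrated depth-dose curves as non-negative superpositions of
    pristine Bragg peaks (effective energy spectra), extracts distal R80
    ranges and R80 energies, fits spot-profile Gaussian sigmas and
    Fermi-Eyges phase-space moments across measurement planes, and compares
    distributions with a 1-D/2-D gamma-index engine. Includes a synthetic
    two-gantry data generator emulating water-phantom commissioning
    measurements and a model-sharing patient-specific QA study with paired
    statistics.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
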