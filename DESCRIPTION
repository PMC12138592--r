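Package: ligalign
Title: Alignment and Density-Map Management for Ligand-Bound Structure Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless pipeline for managing series of ligand-bound
    macromolecular structures, as produced by fragment-screening and
    structure-based drug-design campaigns. Structures are superposed onto a
    common single-chain reference with an iterative Kabsch fit, expanded with
    crystallographic symmetry mates contacting the ligand, and trimmed to the
    binding-site environment. Weighted 2Fo-Fc map coefficients (MTZ) or direct
    real-space maps (CCP4/MRC) are turned into sigma-scaled density fragments
    carried into the reference frame with the superposition transform. The
    grouped scene is emitted as standard-format coordinate and map files plus
    a molecular-viewer script, together with a machine-readable run report.
    A synthetic-fixture generator builds toy protein-ligand crystals and map
    coefficients so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
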