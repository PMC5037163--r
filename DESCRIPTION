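Package: emcoloc
Title: Colocalization Coefficients for Dual-Labeled Point Patterns in
    Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies colocalization between two particle labels in
    immunogold electron-microscopy images treated as planar point
    patterns.  Implements the three-stage coefficient system (per-image
    particle frequencies, relative aggregated colocalization, relative
    colocalization density with optional boundary-correction weights),
    their algebraic consistency checks, a pair cross-correlation
    function with Monte-Carlo envelopes under complete spatial
    randomness for choosing the colocalization distance band, and
    pixel-overlap Manders coefficients for comparison with fluorescence
    microscopy.  Includes a synthetic point-process generator (CSR,
    linked pairs, Thomas clusters) and a command-line interface.
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
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
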