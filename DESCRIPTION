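Package: cgbonded
Title: Multiobjective Calibration of Bonded Parameters in Coarse-Grained
    Lipid Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Automatic calibration of the bonded terms (harmonic bonds and
    angles) of Martini-style coarse-grained lipid models against mixed
    top-down and bottom-up objectives.  Bonded terms are classified into
    building blocks shared across lipid types, scored with a composite
    loss that combines percentage deviations of bilayer observables (area
    per lipid, head-to-head thickness) from experimental targets with
    Wasserstein distances between candidate and reference bond/angle
    distributions, and optimized with a fuzzy self-tuning particle swarm.
    Includes trajectory mapping onto coarse-grained representations,
    bilayer observable analysis, a LENS-based gel/liquid phase classifier,
    GROMACS topology interchange, and a deterministic surrogate simulation
    backend for engine-free end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
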