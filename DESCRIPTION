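Package: forcemapr
Title: Force-Map Analysis of Cell Stiffness by AFM Indentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for atomic force microscopy (AFM) force
    maps of living cells indented with a colloidal (spherical) probe.
    Implements the Hertz-Sneddon spherical-indenter contact model with an
    exact numerical inverse, probe calibration (hard-surface deflection
    sensitivity, thermal-noise spring constant), per-curve contact-point
    estimation and robust Young's-modulus fitting on the approach segment,
    a five-rule quality-control filter cascade, assembly of co-registered
    stiffness and height maps with substrate-plane removal, height-based
    partition of cells into lower and upper regions, and per-timepoint
    stiffness statistics for post-thaw monitoring. A synthetic force-map
    generator simulates phantom cells with known ground truth so every
    pipeline stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
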