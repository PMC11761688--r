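Package: paintkit
Title: Simulation and Analysis Pipeline for PAINT Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for transient-binding (PAINT-style) single-molecule
    localization microscopy in live cells: a stochastic simulator of
    binding-site scenes, binding kinetics and camera frame stacks; spot
    detection and sub-pixel 2D Gaussian fitting with Thompson-style
    localization precision; precision filtering; frame-linking of repeated
    localizations into binding events and residence-time estimation;
    super-resolution reconstruction (histogram and Gaussian rendering,
    temporal color coding, moving-window stacks); Fourier ring correlation
    resolution estimation including resolution versus integration time;
    DBSCAN nanocluster analysis with convex-hull area and axis-ratio
    eccentricity; and nearest-neighbor local density mapping. Reads and
    writes ThunderSTORM-style localization tables and multi-page TIFF
    stacks, and ties all stages into a reproducible, seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
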