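Package: ecsnano
Title: Nanoscale Morphometry of Brain Extracellular Space from
    Single-Nanotube Tracking and Electron-Microscopy Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of the brain extracellular space (ECS)
    at the nanoscale. Implements the full single-walled carbon nanotube
    (SWCNT) tracking pipeline: sub-pixel localization by asymmetric
    two-dimensional Gaussian fitting, redundant cross-correlation (RCC)
    drift correction, trajectory linking, instantaneous-MSD diffusivity
    estimation against the rod free-diffusion reference, local-dimension
    estimation from trajectory confinement, and super-resolved map
    rendering. Also provides morphometry of segmented electron-microscopy
    ECS masks (volume fraction, skeleton longest shortest paths, exact
    local thickness, width categories), matrix-network statistics
    (stained-area fraction, box-counting fractal dimension, skeleton
    lengths), optical-fractionator stereology arithmetic, and the
    accompanying statistical comparisons. A synthetic-data module
    generates ground-truth geometries, confined Brownian walkers, camera
    movies, EM-like masks and reference fractals so every stage is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    minpack.lm,
    tiff,
    png,
    yaml,
    jsonlite,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
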