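Package: spcryolm
Title: Single-Particle Cryo-Light Microscopy Analysis of Trimeric
    Membrane Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for polarization-resolved single-particle
    cryogenic light microscopy of trimeric membrane proteins such as the
    mechanosensitive channel PIEZO1. Provides a synthetic-data generator
    for fluorophore-labeled trimers (blinking kinetics, frozen dipole
    polarization, orientation sampling, localization noise), band-pass
    spot detection, change-point decomposition of polarization time
    traces into dipole states, per-fluorophore localization with
    precision estimates, projected-triangle distance statistics with
    Gaussian-mixture class discovery, rotational template alignment and
    classification, simulated-annealing 3D orientation estimation, and
    conversion of interblade distances to membrane dome curvature radii,
    including a generic rigid-body blade-rotation scan for atomic models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    mclust,
    stats,
    utils,
    graphics
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
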