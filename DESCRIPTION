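Package: polbiref
Title: Polarized-Light Birefringence Contrast Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mueller/Stokes simulation and analysis chain for orientation-dependent
    birefringence contrast in cross-polarized confocal imaging. Models the generation
    of radially polarized light by an eight-sector half-wave spatially variable
    retarder, simulates a rotating circular-polarizer Stokes polarimeter with an
    8-bit averaging camera and reconstructs per-pixel Stokes parameters by least
    squares, renders cross-polarized confocal images of a birefringent fiber (hair)
    under linear, circular and radial illumination, and computes the ratio-contrast
    statistic R between fiber and background from randomly placed regions of
    interest, including depth profiles with depolarization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
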