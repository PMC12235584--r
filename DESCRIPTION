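Package: mimicscope
Title: Characterization Pipeline for Lipid-Coated Nanocapsule Mimics of
    Extracellular Vesicles
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for designing and characterizing extracellular-vesicle
    mimics built from lipid-coated hollow organosilica nanocapsules. Computes
    the coating stoichiometry budget (hollow-shell mass model against a
    two-leaflet area-based lipid mass model, frequency-weighted over a
    nanocapsule size distribution); implements a spectrally resolved
    single-molecule localization (sPAINT) analysis chain with Nile Red
    polarity read-out: Gaussian PSF detection and fitting, redundant
    cross-correlation drift correction, density filtering, grating dispersion
    calibration, per-localization emission-spectrum extraction and Gaussian
    peak fitting, quality-control filtering, flat-kernel mean-shift particle
    clustering, bright/dark-time kinetics, and population-level wavelength
    histogram comparison; and membrane structure/dynamics estimators (area
    per lipid, head-to-head bilayer thickness, area compressibility modulus,
    lateral diffusivity by the Einstein relation) for head-group trajectory
    tables. A seeded synthetic-data module generates ground-truthed movie
    stacks, localization tables, size distributions, and Brownian bilayer
    trajectories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
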