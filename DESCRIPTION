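Package: besselao
Title: Focal-Plane Adaptive Optics for Bessel-Focus Two-Photon Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for adaptive-optics (AO)
    Bessel-focus two-photon fluorescence microscopy. Computes
    aberration-correcting phase patterns for a spatial light modulator
    conjugate to the objective focal plane from pupil-plane corrective
    wavefronts (Zernike fitting, annular masking, Fourier propagation, and
    inverse-transform validation); simulates Gaussian- and Bessel-focus
    two-photon point-spread functions under arbitrary Zernike aberrations
    with a scalar Debye model; simulates pupil-segmentation indirect
    wavefront sensing and modal wavefront reconstruction from bead-image
    displacements; renders bead and dendrite/spine phantoms and their
    Gaussian z-stack or single-sweep Bessel projection images with
    Richardson-Lucy deconvolution; and analyses trial-structured
    drifting-grating fluorescence sessions (dF/F0, evoked responses,
    one-way-ANOVA orientation selectivity, bimodal-Gaussian tuning fits,
    global orientation selectivity index, dominant-orientation histograms)
    with a matching synthetic session generator.
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
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
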