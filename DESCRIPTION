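Package: eptycho
Title: Low-Energy Electron Ptychography with Diffraction-Distortion Self-Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for ptychographic reconstruction of 4D-STEM (scanning
    transmission electron microscopy) datasets acquired at low beam energies.
    Implements iterative phase-retrieval engines (ePIE, least-squares
    maximum-likelihood and its multi-slice extension) with mixed probe modes,
    a floating validity mask, an incoherent-background model and
    super-resolution diffraction padding; a self-calibrating correction of
    pincushion distortion in the diffraction plane, fitted against a powder
    diffraction reference and applied with count-conserving resampling;
    Fourier ring correlation resolution assessment against the half-bit
    information threshold; electron-optical bookkeeping (relativistic
    wavelength, diffraction-limited resolution, dose, detector count budget,
    probe aberrations); and a synthetic 4D-STEM simulator (multi-slice
    forward model, Poisson detector, dead-region mask, injected distortion)
    used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    generics,
    data.table,
    jsonlite,
    yaml,
    png,
    tiff,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
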