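Package: hcfit
Title: Hansen-Coppens Multipole Model Refinement and Charge-Density
    Comparison for Theoretical Structure Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits Hansen-Coppens pseudo-atom multipole models to static
    (thermally unsmeared) structure factors of isolated molecules placed in
    a large pseudo-cubic cell, and compares the resulting charge density
    against a reference density.  Provides Slater-type radial-function
    databanks, analytic aspherical scattering factors with a grid-FFT
    oracle, constrained damped Gauss-Newton refinement with a fixed scale
    factor, electron-density and electrostatic-potential grids in Gaussian
    cube format, grid-based QTAIM basin integration over unified basins,
    iso-density surface extraction with surface-averaged electrostatic
    potential statistics (ME/MAE/RMSE), and a seedable synthetic reference
    generator that emulates wavefunction-like densities by adding small
    charge-neutral bond-density features a multipole model cannot represent.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
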