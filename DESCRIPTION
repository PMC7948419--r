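Package: guvquant
Title: Quantitative Fluorescence and Morphometry Analysis of Giant
    Unilamellar Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measurement chain for membrane-biophysics experiments on
    giant unilamellar vesicles (GUVs): Gaussian-ring contour fitting of
    equatorial confocal sections, fluorescence-to-surface-density
    calibration against mol% dye standards, hydrodynamic-radius based
    footprint and membrane-coverage estimates for disordered peptides,
    membrane-tether curvature-sorting coefficients, micropipette
    aspiration tension, FRAP recovery analysis, and vesicle-tubule
    morphometry on electron-micrograph-style images.  Includes synthetic
    image generators with known ground truth so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
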