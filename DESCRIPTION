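Package: PolStokes
Title: Full-Stokes Polarized Hyperspectral Microscopy: Simulation,
    Reconstruction and Spectral Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mueller-calculus simulation and data reduction for a dual-modality
    polarized hyperspectral / polarized light microscope aimed at white blood
    cell visualization. Provides a forward model of a polarization state
    generator/analyzer built from two polarizers and two liquid crystal
    variable retarders, a synthetic blood-smear phantom generator with
    granulocyte-, lymphocyte- and monocyte-like cells, full-Stokes
    reconstruction from four analyzer intensity cubes, degree-of-polarization
    (DOP/DOLP/DOCP) maps with physicality handling, hyperspectral-to-RGB
    rendering through eye-like spectral response curves, ROI mean-spectrum
    extraction, and per-band two-sample t-tests for comparing cell classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
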