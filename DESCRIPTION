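Package: capdiff
Title: Protein Diffusion Coefficients from Capillary-Tube Fluorescence Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates effective diffusion coefficients (D_eff) of proteins
    through hydrogels from time series of fluorescence images of
    hydrogel-filled capillary tubes with a protein reservoir at one end.
    Provides the semi-infinite one-dimensional Fickian model (complementary
    error function profile), a Crank-Nicolson finite-difference forward
    solver of the capillary geometry for verification, a seeded synthetic
    image-stack generator with detector noise and concentration-intensity
    saturation, reservoir-normalized axial profile extraction, constrained
    nonlinear least-squares fitting of D_eff with the low-intensity /
    far-from-interface filtering rules, chi-square profile-agreement tests,
    replicate summaries, and a parameter-recovery benchmark harness.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    grDevices,
    jsonlite,
    methods,
    optparse,
    stats,
    tiff,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
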