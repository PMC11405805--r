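Package: tirfkin
Title: Single-Molecule TIRF Membrane-Binding Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of single-molecule TIRF microscopy
    experiments on supported lipid bilayers and cell membranes. Provides a
    ground-truthed simulator of membrane-binding events (Poisson arrivals,
    exponential-mixture dwell times with photobleaching censoring, one- or
    two-species 2D Brownian diffusion, Gaussian-PSF movie rendering),
    Laplacian-of-Gaussian spot detection and linear-assignment particle
    linking with the standard trajectory filters, dwell-time survival
    analysis with one- and two-exponential fits and F-test model selection,
    step-size (Rayleigh mixture) diffusion-coefficient fits, association
    rate constant (kON) estimation by binding-frequency versus concentration
    regression, and bulk membrane-recruitment kinetics (fold change,
    reaction half-time, lipid surface density).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
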