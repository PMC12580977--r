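Package: laurdanGP
Title: Laurdan Generalized Polarization Analysis of Lipid Phase
    Transitions in Vesicles and Nanodiscs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of temperature series of Laurdan
    emission spectra from lipid vesicles and membrane-scaffold-protein
    nanodiscs. Computes generalized polarization (GP) curves from emission
    spectra, extracts melting temperature, cooperativity and transition
    area from the negative first derivative of the GP thermogram via
    central finite differences, fits a two-state melting model by
    nonlinear least squares, evaluates a fixed-width boundary-lipid
    geometric model of nanodisc rim perturbation, and performs grouped
    relative-abundance normalization of lipid-species intensity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
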