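Package: muxspec
Title: Simulation and Sparse Reconstruction for Liquid-Crystal Multiplexed
    Hyperspectral Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward model of a two-cell liquid-crystal spectral modulator
    placed between crossed polarizers, simulation of compressive
    hyperspectral acquisition (a few multiplexed grayscale frames instead
    of hundreds of narrowband exposures), and per-pixel spectral recovery
    with TwIST and orthogonal matching pursuit solvers over analytic or
    learned sparsifying dictionaries. Includes seeded phantom generators
    (bandpass filter spectra, H&E-like two-class tissue cubes, edge
    resolution targets), evaluation tools (spectral PSNR, edge-based MTF,
    multispectral band binning, class-envelope separability), ENVI/TIFF
    cube input and output, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'lc-model.R'
    'sensing.R'
    'sparsify.R'
    'solvers.R'
    'evaluate.R'
    'phantoms.R'
    'io.R'
    'cli.R'
    'muxspec-package.R'
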