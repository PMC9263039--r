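Package: holoassay
Title: Label-Free Cytotoxicity Assays by Digital Holographic Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of digital holographic microscopy (DHM)
    cytotoxicity assays on adherent cell cultures. Generates synthetic time-lapse
    off-axis hologram stacks of cell populations responding to detergent or
    cytostatic agents, reconstructs averaged quantitative phase images by Fourier
    sideband demodulation with optional numerical refocusing and phase unwrapping,
    and derives the assay readouts: cellular dry mass from the mean phase shift via
    the specific refractive increment, 12-hour dry-mass increments, and the
    fraction of rounded cells from circularity-based single-cell morphometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'optics.R'
    'footprint.R'
    'simulate.R'
    'render.R'
    'holo_io.R'
    'recon.R'
    'unwrap.R'
    'background.R'
    'morphometry.R'
    'drymass.R'
    'pipeline.R'
    'zzz.R'
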