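Package: polarLD
Title: Quantitative Fluorescence-Detected Linear Dichroism Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Visualization, quantitation and physical interpretation of
    fluorescence-detected linear dichroism (LD) in polarization-resolved
    microscopy images. Implements the photoselection forward model mapping
    wrapped-Gaussian fluorophore tilt-angle distributions to dichroic
    observables under one- and two-photon excitation, de-interleaving and
    correction of polarization-modulated images, per-pixel harmonic fits of
    multi-polarization stacks, spline-based assignment of membrane or
    filament orientation to pixels, parametric fitting of dichroic-ratio
    curves, goodness-of-fit maps over the tilt-distribution parameter grid
    with bootstrap confidence regions, two-Gaussian mixture searches, and a
    synthetic-scene generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    minpack.lm,
    pracma,
    tiff,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'io.R'
    'orientation-model.R'
    'polarLD-package.R'
    'polarization-image.R'
    'quantify.R'
    'render.R'
    'show-methods.R'
    'simulate.R'
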