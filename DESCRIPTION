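Package: doct
Title: Dynamic Optical Coherence Tomography Viability Mapping for 3D Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies site-dependent cell viability in three-dimensional cell
    spheroids from dynamic optical coherence tomography (D-OCT) time-series
    image stacks. Computes per-pixel Welch power spectral densities of the
    intensity fluctuations, derives mean-frequency, frequency-bandwidth and
    amplitude maps, renders HSV pseudo-color images, segments viable and
    necrotic cell layers by a mean-frequency threshold with edge-artifact
    correction, and summarises viability across depth and culture time. A
    synthetic spheroid phantom generator with known per-layer temporal spectra
    and ground-truth labels replaces the instrument for testing and simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    tiff,
    png,
    yaml,
    jsonlite,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
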