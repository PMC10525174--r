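Package: directECGI
Title: Direct Inverse Electrocardiographic Imaging via Huygens Surface
    Sources and Eigenfunction Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Non-iterative reconstruction of epicardial potential sources
    from body-surface ECG recordings.  Interpolated electrode potentials on
    the torso surface are treated as secondary Huygens sources, expanded in
    eigenfunctions of the finite-element conductivity operator of a
    hexahedral volume-conductor model, and projected onto the epicardium to
    obtain equivalent voltage sources.  Includes trilinear hexahedral FEM
    assembly, mass-orthonormal eigenbasis computation with energy-based
    spectral truncation, pyramid-patch interpolation of sparse electrode
    layouts, a forward solver for self-validation against the original
    recordings, and a parametric synthetic torso generator with a
    PQRST-like epicardial activation model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
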