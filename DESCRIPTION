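Package: oslmorph
Title: 3D MicroCT Morphometry of the Osseous Spiral Lamina
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative three-dimensional morphometry of the cochlear
    osseous spiral lamina (OSL) from microCT-style image stacks:
    threshold segmentation with artifact removal, geometric separation of
    the vestibular and tympanic plates, mesh-volume porosity via a
    filled (pore-free) morphological envelope, spiral-coordinate width
    and thickness profiling, and pore spatial-distribution maps.
    Includes a synthetic conical-spiral phantom generator with exact
    voxel-level ground truth for validating every pipeline stage, plus
    TIFF/STL/CSV/JSON input-output and a command-line entry point.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
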