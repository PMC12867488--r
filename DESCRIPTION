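Package: strokevol
Title: Lesion Volumetry for Cleared-Brain Light Sheet Imaging of Photothrombotic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-automated quantification of ischemic lesion volume from 3D
    autofluorescence volumes of optically cleared mouse brains, together with
    the cross-modality estimators used to validate it: slice-based (MRI- and
    histology-style) volumetry, laser speckle contrast imaging of
    hypoperfusion, clearing-shrinkage accounting, and simple linear regression
    for cross-modality agreement. Includes a seeded synthetic phantom
    generator that produces ground-truth lesions with co-registered
    light-sheet-like, MRI-like, histology-like and speckle modalities, so the
    whole pipeline is testable at desk scale, and a command-line interface
    with JSON provenance records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    RNifti,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
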