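Package: plexquant
Title: Quantification of Inflammatory Infiltrates in Multiplex
    Immunofluorescence Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantitative analysis of multiplex tyramide signal
    amplification (mTSA) stained tissue imaged multispectrally, with kidney
    transplant biopsies as the motivating application. Decomposes multispectral
    tiles into per-fluorophore abundance planes by non-negative least squares
    against a spectral library, stitches tiles into whole-slide planes,
    synthesizes artificial brightfield immunohistochemistry (hematoxylin/DAB)
    images from DAPI and marker planes via Beer-Lambert stain vectors, decodes
    detector outputs (probability maps, box grids) into point detections,
    scores detections against dot annotations (radius matching with
    closest-detection tie-break; precision/recall/F1), and computes cell
    densities, double positivity, nearest-neighbour distances and
    positive-pixel fractions inside annotated regions of interest, with a
    group-comparison statistics layer. Includes a synthetic-scene generator
    that renders ground-truthed cells through a known spectral library so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils,
    xml2
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
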