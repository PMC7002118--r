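Package: extremecell
Title: Geometry-Aware Extreme-Point Cell Detection with Adjacency-Spectrum Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoder-side implementation of geometry-aware extreme-point cell
    detection for microscopy images. Extracts top/left/bottom/right extreme
    points and center points from keypoint heatmaps (3x3 local-maximum peak
    extraction with sub-cell offset refinement), groups them into candidate
    cells by brute-force center grouping, and verifies each candidate against a
    per-class reference of adjacency spectra: the eigenvalues of the
    Euclidean-distance-weighted 4-cycle graph on the extreme points, a
    rigid-motion-invariant shape signature that rejects cross-cell keypoint
    combinations between juxtaposed cells. Includes the associated training
    losses (modified focal loss, smooth-L1 offset loss) as pure functions, a
    synthetic microscopy-scene simulator (round nuclei, crescent, spindle and
    pear shaped parasites) that renders the keypoint heatmaps a trained network
    would output, COCO-style average-precision evaluation, and readers/writers
    for LabelMe and COCO JSON annotation formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    png,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
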