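Package: fibertrack
Title: Microscopic Tractography for Serial Block-Face Microscopy Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate local fiber orientation in large serial
    block-face microscopy stacks of peripheral nerve and to propagate,
    constrain, edit and evaluate streamline tractograms. Orientation is
    estimated either by pyramidal Lucas-Kanade optic flow between
    consecutive slices or by eigen-analysis of the 3D structure tensor
    computed in overlapping chunks on near-isotropic resampled data.
    Streamlines are seeded deterministically from labelled regions of
    interest, terminated when they diverge more than a set angle from the
    stack axis, and can be restricted to fascicle masks (anatomically
    constrained tractography). Tractograms are scored against ground-truth
    fiber-group masks with a normalized Dice overlap and compared with each
    other through a mean closest-neighbor distance over QuickBundles-style
    cluster centroids. A synthetic fiber-phantom generator with known
    trajectories makes every stage testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    pracma,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
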