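Package: stalkfield
Title: Individual Maize Segmentation from Terrestrial LiDAR Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments individual maize plants from terrestrial laser scanning
    (TLS) point clouds of young maize fields. The cloud is sliced from many
    azimuthal viewing directions into thin 3D windows, each window is
    compressed to a depth image, stem candidates are detected on the images
    with a confidence-scored bounding-box detector, surviving detections are
    mapped back to 3D stem seed points, and every remaining point is assigned
    to a plant by comparative shortest-path region growing in which graph
    transport distances are scaled by stem diameter to the power 2/3.
    Includes a labelled synthetic maize-field generator, ground filtering by
    a per-cell elevation threshold, plant-level precision/recall/F-score
    evaluation against reference labels, and plant-height extraction with
    regression diagnostics. Point clouds are read and written as ASCII XYZ,
    PLY, and LAS 1.2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    EBImage,
    igraph,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
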