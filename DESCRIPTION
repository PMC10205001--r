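Package: brainmapr
Title: Whole-Brain Cell Mapping for Cleared-Tissue Light-Sheet Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for mapping labeled cells in cleared
    whole-brain light-sheet image stacks onto a hierarchical reference atlas.
    Detects cells by background subtraction, band-pass filtering and
    marker-controlled watershed (or imports externally segmented coordinates),
    fits landmark-based affine and thin-plate-spline transforms from sample to
    atlas space, assigns cells to hierarchical brain regions and aggregates
    region counts and densities, builds voxel-level density heatmaps and
    group-comparison p-value maps, and projects cortical cells onto a
    flattened-cortex map with a Laplace-equation depth coordinate for layer
    profiles. A synthetic-data module generates toy atlases, planted cell
    populations and simulated stacks with known ground truth so the whole
    pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
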