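Package: trackmix
Title: Simulation and Mixture-Based Diffusion Analysis of Single-Molecule
    Tracks in Bacterial Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-molecule microscopy (SMM) of diffusing
    fluorescent proteins in rod-shaped bacteria. Simulates multi-population
    Brownian motion confined to spherocylindrical cells (with photobleaching,
    localization noise and focus-anchored molecules), renders synthetic image
    stacks, detects and links spots, and recovers population structure from
    track tables: frame-to-frame displacement statistics, zero-mean Gaussian
    mixture fits, jump-distance (squared-displacement) mixture fits with
    shared global diffusion constants across conditions, mean-squared
    displacement analysis, standardized-cell track-density maps, dwelling
    classification, replisome-focus detection and nearest-focus distance
    histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
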