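Package: ramtrack
Title: Bitmap-Based Rat Tracking and Behavioral Scoring for Radial Arm
    Maze Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates a rat in infrared video frames of an eight-arm radial
    maze using simple binary image operations (thresholding, maze-mask
    intersection, morphological opening, largest-component selection) and
    scores the resulting trajectory: arm entries and exits, working- and
    reference-memory errors, latency, path length, average speed, zone
    occupancy over an 89-piece maze partition, and still-spot ("S" spot)
    statistics. Includes a ground-truthed synthetic infrared scene
    generator (moving rat blob, dropping noise, out-of-maze clutter,
    intruder occlusion) so the full pipeline can be exercised and
    evaluated without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    png,
    Rcpp,
    readr,
    rlang,
    tibble,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
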