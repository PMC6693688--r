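Package: flashschool
Title: Agent-Based Modelling and Low-Light Video Analysis of
    Bioluminescent Fish Schooling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying collective motion mediated by
    bioluminescent flashing, motivated by nighttime schooling of the
    flashlight fish Anomalops katoptron. Provides a 3-D agent-based
    school simulator with flash-gated social forces (cohesion,
    alignment, separation) and informed-leader overrides; synchrony
    statistics (the mSync polarization order parameter, direction
    correlation with motivated individuals, a random-motion null and a
    Wilcoxon rank-sum comparison); a low-light video pipeline
    (fixed-pattern-noise estimation and subtraction, thresholding,
    morphological cleanup, area-filtered centroid detection, and
    greedy nearest-neighbour track linking); flash-kinetics analysis
    (on/off durations, duty cycles, blink rate, power spectra); a
    Beer-Lambert starlight-attenuation utility; and a ground-truthed
    synthetic-scene generator emulating sparse 16-bit low-light
    recordings of moving, flashing fish.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    igraph,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
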