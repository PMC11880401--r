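Package: crtclust
Title: Movement-Pattern Clustering of Five-Times Chair-Rise Force-Plate Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the five times chair rise test (5CRT) from
    vertical ground-reaction-force recordings. Provides a calibrated synthetic
    cohort generator with a ground-truth channel, automatic detection and
    segmentation of the five chair-rise cycles, extraction of the Schenkman
    phase forces (seat-unloading, seat-off, stabilization, standing), an exact
    dynamic time warping (DTW) implementation with path recovery, DTW barycenter
    averaging (DBA) and soft-DTW barycenters, DTW-metric k-means clustering of
    chair-rise waveforms with silhouette and Davies-Bouldin validation, SPPB
    chair-rise scoring, and the cohort-level comparison statistics (Mann-Whitney
    tests, stopwatch versus force-plate duration regression, cluster-consistency
    tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
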