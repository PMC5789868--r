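Package: tagqc
Title: Quality Control for Passive Acoustic Telemetry Detections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated per-tag quality control for continental-scale passive
    acoustic telemetry detection data. Screens detections of coded acoustic
    transmitters with a false-detection (interval-ratio) algorithm, movement
    plausibility tests based on over-water least-cost distances and swim
    speeds, species expert-distribution checks, and release date and location
    checks, combining five of these tests into a composite four-level validity
    flag per detection. Includes a rasterised land/water cost surface with a
    grid shortest-path engine, river-to-coast composite distances, a trip
    distance cache, readers and writers for the detection and tag-metadata
    CSV schemas, a synthetic scenario generator with known injected
    contamination for end-to-end testing, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
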