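Package: passrhythm
Title: Pass-Possibility Networks and Graph Visual Rhythms for Soccer
    Possession Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-frame pass-possibility graphs for both teams from
    player tracking data (Delaunay triangulation with an opponent-marking
    filter), computes eight per-vertex complex-network metrics (betweenness,
    eccentricity, global and local efficiency, vulnerability, clustering,
    h-step random-walk entropy, PageRank), encodes the metric time series of
    a ball-possession interval as a 16-channel visual-rhythm image, trains a
    convolutional classifier that predicts whether the attacking team will
    reach the attacking zone (final quarter of the pitch), and attributes
    predictions to metrics with Shapley-value estimates from a kernel-weighted
    local linear surrogate. Includes an Ornstein-Uhlenbeck tracking-data
    simulator with a plantable defending-team tactical signal so the whole
    pipeline is testable without real match data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
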