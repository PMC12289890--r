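Package: crowdcount
Title: Aggregation and Validation of Crowdsourced Wildlife Counts from
    Aerial Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for turning raw volunteer classifications of aerial image
    tiles into consensus wildlife detections and counts, and for validating
    those against an expert gold standard. Implements consensus presence via
    minimum-agreement thresholds and majority vote, four count-aggregation
    methods (median, mode with max tie-break, DBSCAN and HDBSCAN spatial
    clustering of volunteer point marks), accuracy metrics with an exact
    under/overcount decomposition, quasi-Poisson comparisons of counting
    methods with multiplicity-adjusted pairwise contrasts, and a volunteer
    simulator that reproduces the statistical structure of a marine iguana
    drone-survey citizen-science campaign for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
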