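Package: cohortnet
Title: Group-Level Analysis of Weighted Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds weighted functional and structural brain networks from
    region-of-interest (ROI) time series and fiber-count matrices, computes
    small-world and efficiency metrics normalized against degree-preserving
    null ensembles, and compares subject groups with permutation statistics.
    Includes a synthetic-cohort generator with controllable group effects on
    network topology, so the full pipeline can be exercised and validated
    without access to imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
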