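Package: spermosaic
Title: Germline Mosaicism from Digital PCR and Spermatogonial Clone Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies rare variant allele frequencies in sperm and testis
    DNA from digital-PCR compartment counts (Poisson occupancy correction,
    reaction merging, spike-in calibration, cross-platform comparison),
    analyses donor cohorts for paternal-age effects (Spearman age
    association with Benjamini-Hochberg control, age-group contrasts,
    summary tables), summarises the spatial clustering of mutations in a
    dissected testis (piece pooling, hot-pool drill-down, Max/IQR
    clustering statistics), and fits two branching-process models of
    spermatogonial stem-cell dynamics (symmetric hot-spot and symmetric
    selection) by matched-simulation search with a Monte-Carlo
    maximum-statistic hypothesis test. Synthetic-data generators emulate
    the sampling designs so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
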