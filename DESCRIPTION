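Package: rootbench
Title: Benchmarking Gene Tree Rooting Methods for Prokaryotic Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates prokaryotic gene family evolution with duplication,
    horizontal transfer (additive and replacing), and loss inside birth-death
    species trees; roots the resulting unrooted gene trees with midpoint,
    minimal ancestor deviation (MAD), minimum variance (MV), parsimonious
    duplication-transfer-loss (DTL) reconciliation, and random rooting; and
    scores rooting accuracy with clade-based Robinson-Foulds distances,
    adjusted RF for error-prone topologies, and root balance statistics.
    Includes an experiment pipeline that reproduces the full simulation grid
    (event-rate presets, branch-scaling schemes, DTL event-cost sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
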