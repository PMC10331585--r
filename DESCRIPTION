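Package: nmjscreen
Title: Multilevel Phenotypic Drug-Screen Analysis for Zebrafish
    Neuromuscular Disease Models
Version: 0.1.0
Authors@R:
    person("NMJ Screen", "Developers", email = "nmjscreen@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for plate-based behavioral drug screens in
    zebrafish larvae and their downstream refinement filters: robust
    z-score hit calling with Z'-factor assay quality, normalized percent
    activation rescreening, drug-target recurrence network filtering,
    high-content neuromuscular junction (NMJ) image quantification
    (acetylcholine-receptor cluster detection, axon individualization and
    length, axon/cluster co-localization), and multi-parameter cellular
    hit refinement with nonparametric group statistics. Includes a
    synthetic-data module that generates behavioral screen tables,
    drug-target interaction tables, and two-channel NMJ micrographs with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
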