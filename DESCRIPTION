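Package: virorules
Title: Association-Rule Mining of Mycovirus Co-Occurrence in Fungal Strain Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines co-occurrence rules among viruses from a binary
    strains-by-viruses presence/absence matrix using the Apriori algorithm
    over present/absent items, with Support, Confidence and Lift metrics.
    Significance is assessed by a permutation null model with a dynamic,
    stratum-specific Lift threshold calibrated so that the false-positive
    rate among retained rules stays below a target (default 5%). Includes
    rule typing (presence/absence pattern classes), validation of mined
    rules against the virus compositions of single-spore offspring and
    transfectants, a synthetic-data generator with planted dependencies for
    closed-loop testing, and a single-command pipeline with tabular and
    JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
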