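Package: labelaudit
Title: Seafood Label Authentication from DNA Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end authentication of seafood market labels against
    DNA-barcode (COI) species identifications. Implements quality
    trimming and pairwise consensus calling for paired Sanger reads,
    curation and filtering of reference-database hit tables, taxonomic
    assignment, resolution of market-label terms to permitted species
    sets under alternative label-to-species definition regimes,
    detection of non-standard (misnamed) labels, mislabelling-rate
    estimation with Wald and Goodman simultaneous confidence intervals,
    and a right-censored survival model that standardises mislabelling
    rates to species-level label resolution via AIC model averaging.
    Includes a synthetic-data generator emulating a national market
    survey so the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    MASS,
    splines,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
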