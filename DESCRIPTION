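Package: mimoscan
Title: Mapping Phage-Display Mimotopes to Candidate Tumor-Associated Antigens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analyzing random-peptide phage-display biopanning output
    against serum antibodies. Short peptides selected on patient antibodies are
    searched against a protein database with a transparent ungapped matcher tuned
    for 4-6 residue motifs, a chance-match null is estimated from the same
    peptides in reverse orientation ("spelt backwards" decoys), and candidate
    antigen proteins are ranked per patient panel with length-normalized binomial
    tail probabilities and Fisher's exact contrasts, after collapsing matches
    that are redundant through a shared motif. Includes conserved-motif
    extraction for peptide panels, a seeded synthetic-data generator with
    planted ground truth, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
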