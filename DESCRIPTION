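Package: oxpair
Title: Phylogenomic Survey of the Oxidizable CaMKII Regulatory Residue Pair
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-anchored classification of the CaMKII regulatory-domain
    residue pair at positions 281/282 (CaMKII-gamma numbering) across metazoan
    protein sequences, together with clade- and species-level conservation
    statistics, Fitch/Hartigan parsimony reconstruction and dating of the
    character's origin on a supplied taxonomy tree, verification utilities for
    CRISPR HDR knock-in edit designs, and a sequence-evolution simulator with a
    planted character history so that every stage of the survey is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
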