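Package: parafind
Title: Parasite Identification and Richness Analysis for eDNA Metabarcoding Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Identifies putative eukaryotic parasites among amplicon sequence
    variants (ASVs) from environmental DNA metabarcoding surveys by combining
    similarity-search hits against custom reference collections, host metadata
    attached to reference records, and literature evidence of parasitism, with
    rule-based exclusion of abiotic, non-living-substrate and symbiont records.
    Provides negative-control decontamination of ASV count tables, indicator
    analysis of habitat preference via a presence/absence permutation test with
    Sidak correction, Poisson richness models with Type-III Wald tests and
    deviance-based partial R-squared, and a seeded synthetic-study generator
    emulating a paired heated/control lake survey for validation and power
    analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    car,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
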