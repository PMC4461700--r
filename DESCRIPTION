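Package: imprintscan
Title: Epimutation Screening at Imprinted Loci from Methylation-Sensitive
    Digest Fragment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-locus methylation and gene dosage at imprinted
    differentially methylated regions (SNRPN, KCNQ1OT1, H19, MEG3) from
    methylation-sensitive restriction digest multiplex-PCR peak tables,
    classifies epigenotypes (partial/complete loss or gain of methylation,
    dosage changes) with mechanism hypotheses, and confirms or excludes
    uniparental disomy by segregation analysis of trio microsatellite
    genotypes. Includes a synthetic-data generator that emulates the
    molecular structure of the assay (parental-origin copy numbers, mosaic
    methylation fractions, digest survival of methylated template,
    amplicon efficiencies, loading factors, multiplicative peak noise) so
    the whole screen is testable without patient material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
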