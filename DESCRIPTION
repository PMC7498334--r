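Package: ampmeth
Title: Ultra-Deep Amplicon Bisulfite Sequencing Analysis for Imprinted Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for targeted, UMI-tagged amplicon bisulfite sequencing of
    genomic imprints. Defines amplicon panels and checks bisulfite PCR
    primer-design rules, simulates ground-truthed paired-end reads (parental
    alleles, bisulfite chemistry, PCR duplication sharing unique molecular
    identifiers, sequencing error), extracts in-line UMIs, assigns reads to
    amplicons and calls per-CpG methylation in three-letter bisulfite space,
    collapses PCR duplicates by UMI and position, splits reads by parental
    allele using strain SNPs, and quantifies per-CpG, per-read and per-region
    methylation with imprinting-fidelity classification.
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
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
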