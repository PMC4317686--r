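Package: glioseg
Title: Pedigree-Aware Co-Segregation Triage of Familial Glioma Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Staged triage of annotated sequence variants in multiplex
    glioma families: linkage-region and capture-target gating with a
    Cancer Gene Census waiver, population-frequency filtering, family
    co-segregation filtering over pedigree genotypes, bidirectional
    Sanger concordance verification, and CADD scaled C-score ranking of
    the surviving candidates. Includes a seeded gene-drop simulator that
    generates multi-family cohorts with planted segregating candidates
    and per-filter decoy variants, together with a truth table, so the
    whole pipeline is testable without cohort sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
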