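Package: edmdpanel
Title: Multistage Candidate-Gene Discovery for Genetically Heterogeneous
    Muscular Dystrophies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Implements a multistage strategy for candidate-gene discovery
    in genetically heterogeneous Mendelian disease, developed around
    Emery-Dreifuss muscular dystrophy (EDMD).  Provides pedigree-based
    co-segregation filtering of exome variants under declared inheritance
    modes, a two-stage population-frequency cascade, coding-consequence and
    tissue-expression filters; construction of a four-category targeted
    gene panel with target-region emission; cohort-stage patient
    classification with inheritance-consistency checks and
    recurrence-based elevation of exome candidates; and gene-set
    enrichment (exact hypergeometric/binomial) plus protein-interaction
    connectivity statistics for the resulting candidate sets.  A
    synthetic-cohort generator with planted causal alleles and a
    ground-truth ledger supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
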