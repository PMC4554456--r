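Package: colitype
Title: Phylogroup Quantification and Enterocolitype Classification of
    Commensal Escherichia coli Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of commensal Escherichia
    coli population structure from phylogroup-specific quantitative PCR.
    Converts probe counts into phylogroup proportions (A with its A0/A1
    subgroups, B1, B2, D) using the subtraction formula and compositional
    detection thresholds, classifies samples into abundance categories,
    CFU classes, diversity classes and intra-species enterotypes
    ("enterocolitypes"), builds binary indicator tables and ordinates them
    by correspondence analysis, and scores B2 strains for 20
    extraintestinal virulence-factor genes with exact and chi-square group
    comparisons. A seeded synthetic-cohort generator (Dirichlet
    compositions, log-normal total counts, multiplicative qPCR noise with
    limits of detection, Bernoulli gene panels) makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
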