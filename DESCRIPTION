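Package: grsxe
Title: Case-Control Candidate-Gene Association, Genetic Risk Scores, and
    Gene-Lifestyle Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for frequency-matched case-control candidate-gene
    studies: Hardy-Weinberg quality control with permutation correction,
    single-locus logistic association under genotypic, dominant, recessive and
    additive codings with permutation-corrected p-values, classification-tree
    (CART) screening of multilocus genotype combinations with Gini splitting,
    unweighted and weighted genetic risk scores with quartile categorisation,
    and additive- and multiplicative-scale gene-lifestyle interaction measures
    (relative excess risk of interaction, attributable proportion, interaction
    odds ratio) with bootstrap confidence intervals. Includes a synthetic
    cohort generator emulating a frequency-matched childhood-obesity
    case-control design so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
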