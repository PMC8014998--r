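Package: terminomics
Title: Quantitative N-Terminomics (TAILS) and Protease Substrate-Trapping Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for quantitative protein N-terminomics by
    Terminal Amine Isotope Labeling of Substrates (TAILS) and for
    affinity-enrichment substrate-trapping screens. Maps identified
    N-terminal peptides onto annotated protein models, classifies termini
    against signal-peptide, mitochondrial-targeting-signal and propeptide
    maturation sites, normalizes and aggregates duplex dimethyl isotope
    ratios, derives robust interquartile-range cutoffs for differential
    terminus calling, profiles cleavage-site specificity with
    positional-enrichment (iceLogo-style) statistics, and classifies
    trapping-screen hits by multi-sample ANOVA with Benjamini-Hochberg
    correction and Tukey post-hoc tests after downshifted-normal
    imputation of missing label-free intensities. Includes a fully
    parameterized synthetic-data generator with recorded ground truth so
    every pipeline stage can be validated without raw mass-spectrometry
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
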