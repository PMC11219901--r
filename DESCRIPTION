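Package: shedscan
Title: Sheddome Discovery and Quantification from Label-Free Proteomics Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and analyses the soluble-fraction "sheddome" -- the
    membrane-anchored (transmembrane or GPI-anchored) subset of proteins
    detected in detergent-free tissue supernatants, which are candidate
    products of ectodomain shedding -- from protein-level label-free
    mass-spectrometry tables. Provides membrane-anchor classification and
    filtered sheddome extraction (molecular-weight and occurrence rules,
    gel-fraction merging), set-overlap statistics (Venn counts, hypergeometric
    tests, analytic and Monte-Carlo fold enrichment), term enrichment against
    a user-supplied background with Benjamini-Hochberg correction, two-group
    differential abundance with left-censored (missing-not-at-random)
    imputation and empirical-Bayes moderated t-tests, peptide-topology
    ectodomain evidence, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
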