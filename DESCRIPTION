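Package: peroxscreen
Title: Comparative Screening for Peroxisome Loss in Predicted Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics screen for the presence or absence of
    peroxisomes across predicted proteomes. Builds per-family scoring
    profiles from marker alignments, calibrates empirical E-values on null
    sequences, assigns proteins to orthologous marker groups with a
    best-versus-next-hit log E-value score, scans peroxisomal targeting
    signals (PTS1/PTS2) with verbatim sequence patterns, classifies
    N-terminal signals, collapses per-protein signals to localization
    categories, calls peroxisome loss from essential-peroxin absence, and
    counts unique orthologous groups as a genome-complexity measure. Ships
    a synthetic-cohort generator with known ground truth so the whole
    pipeline is testable end to end, plus an ingestion backend for real
    HMMER3 domain-table searches and TargetP-style predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
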