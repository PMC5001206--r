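Package: oncoportrait
Title: Multi-Omic Similarity Between Cancer Cell Lines and Primary Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how faithfully cancer cell lines portray primary
    tumors across four molecular layers: mRNA expression, DNA copy number,
    somatic mutation, and (phospho-)protein abundance. Provides breast-cancer
    subtype assignment from ER/PR/HER2 marker rules with nearest-centroid
    expression prediction as fallback, fraction-genome-altered and
    segment-to-gene copy-number summaries, somatic mutation filtering with
    six-category substitution spectra and flanking-context profiles,
    correlation-based layer similarities, and a combined per-cell-line
    suitability score that ranks cell lines by their overall resemblance to a
    tumor cohort. A seeded synthetic matched-cohort generator with planted
    subtype structure makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
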