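Package: metadiet
Title: Multi-Marker DNA Metabarcoding Diet Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-marker DNA metabarcoding diet
    analysis: PCR-replicate quality control by within- versus between-sample
    dissimilarity distributions, global and per-sample MOTU filtering,
    taxonomic-scope restriction per primer set, fusion of specialized marker
    datasets onto a eukaryote scaffold, relative read abundance (RRA) and
    weighted percent of occurrence (wPOO) diet metrics, Hill-number diversity,
    and permutation-based composition statistics (PERMANOVA, PCA/RDA,
    permutation ANOVA). Includes a Dirichlet-multinomial study simulator with
    known ground truth for end-to-end recovery experiments.
License: MIT
Encoding: UTF-8
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
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
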