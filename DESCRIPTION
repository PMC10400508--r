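Package: retproteome
Title: Differential Proteome Screening, Network Hub Discovery and
    Phosphopeptide Analysis for iTRAQ Muscle Ageing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for pooled 4-plex iTRAQ quantitative
    proteomics of skeletal muscle ageing and resistance exercise training
    (RET). Screens quantified-protein tables into per-contrast regulation
    calls with fold-change cut-offs and significance tiers, performs local
    hypergeometric over-representation analysis of protein lists against
    GMT gene-set collections with Benjamini-Hochberg FDR control, extracts
    first-order and minimum (Steiner-type) interaction subnetworks from a
    protein-protein interactome and ranks hub proteins by betweenness
    centrality, classifies RET-response concordance between age groups and
    RET reversal of baseline age dysregulation, and filters, normalizes and
    tests phosphopeptide tables. A synthetic-data module generates all
    pipeline inputs with known planted ground truth so every stage is
    testable without external downloads.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
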