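Package: mirvar
Title: Precision and Preanalytical Variability Analysis for Circulating
    MicroRNA Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying circulating microRNA levels measured by
    RT-qPCR (single TaqMan assays and low-density arrays) and droplet
    digital PCR, and for characterising the preanalytical and analytical
    variability of such measurements. Implements delta-Ct relative
    quantification and Poisson occupancy concentration estimation under
    spike-in (cel-miR-39), endogenous (miR-16) and combined reference
    strategies; nested intra-/inter-assay coefficient-of-variation
    estimation from duplicate designs; attribution of intra-assay variation
    to plasma preparation and microRNA purification; protocol, material and
    platform comparison statistics; an iterative paired-means sample-size
    calculation; and a hierarchical synthetic-data generator emulating a
    centrifugation-protocol study, a two-material patient cohort and a
    multi-platform precision experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
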