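Package: synspread
Title: Quantification of Trans-Neuronal Alpha-Synuclein Aggregate Transfer
    in Compartmentalized Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the anterograde trans-neuronal transfer of
    fluorescently labelled alpha-synuclein aggregates in unidirectional
    two-compartment ("presynaptic > postsynaptic") microfluidic neuron cultures.
    Provides ROI-based fluorescence quantification with same-session control
    normalization and quality-control rules, the Transmitted Excess Signal (TES)
    statistic with experiment-level aggregation and the accompanying statistical
    comparisons, kymograph construction and particle-transport quantification,
    synaptic-density and pSyn/MAP2 scoring, an equivalent-dose / per-axon
    transfer-rate model, and a seeded synthetic-microscopy generator with ground
    truth so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
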