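Package: gliamod
Title: Satellite Glia Secretome and Sensory Neuron Excitability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how satellite glial cell (SGC) secreted
    factors modulate the excitability of small/medium dorsal root ganglion
    (DRG) sensory neurons. Provides a single-compartment conductance-based
    simulator of a DRG neuron with a Kv4-like A-type potassium current,
    patch-clamp style feature extraction from ramp current-clamp recordings
    (action potential detection, rheobase, state-dependent input resistance),
    voltage-clamp potassium current analysis (P/5 leak subtraction, prepulse
    subtraction to isolate the A-current, capacitance-normalised I-V curves),
    a secretome filtering and matrisome/enrichment pipeline for
    conditioned-media mass spectrometry tables, pseudobulk cell-type
    integration (TMM/log-CPM normalisation, Spearman similarity, SGC
    specificity ranking), and Dixon up-down estimation of the 50 percent paw
    withdrawal threshold from von Frey testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
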