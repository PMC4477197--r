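Package: connstereo
Title: Inter-Individual Stereotypy Analysis of Synaptic Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing single-cell synaptic connectomes between
    individuals. Builds full and cell-type-grouped connectivity matrices from
    neuron and synapse tables, quantifies inter-individual stereotypy with
    Spearman rank correlations and permutation tests, computes geometric-mean
    combined matrices and reciprocal-connection strengths, scores left-right
    asymmetry of bilateral homologs, regresses photoreceptor maturation
    covariates, and summarises motoneuron innervation of ciliary-band and
    muscle effectors. A seedable synthetic paired-connectome generator samples
    individuals from a ground-truth cell-type wiring template with count
    overdispersion, connection dropout, neuron truncation and untraceable
    fragments, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
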