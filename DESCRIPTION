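Package: connectoscope
Title: Network Analysis of Directed Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural analysis of directed, spatially embedded
    brain connectomes at the region (areal) scale. Provides graph statistics for
    directed binary networks (density, reciprocity, degree and betweenness
    tables, clustering, co-occurrence eigenspectra, triad and directed-clique
    censuses), two-block stochastic block model core-periphery inference by
    expectation-maximization with an analytic Erdos-Renyi specificity bound,
    Girvan-Newman onion dendrograms with strongly-connected-component tracking,
    structural controllability via maximum matching and degree-preserving null
    models, an exponential distance rule (EDR) generative network model with
    decay-rate estimation by ensemble property matching, recursive
    coarsening of a connectome to a macro-region quotient network, and
    generators for synthetic spatially embedded connectomes with known ground
    truth. Results are returned as tibbles and fitted objects carry tidy(),
    glance() and autoplot() methods.
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
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
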