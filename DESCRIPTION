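Package: islandDD
Title: Island-Wide and Clade-Specific Diversity-Dependent Island Biogeography Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Birth-death-colonization models of island community assembly with
    linear diversity-dependent feedback on colonization and cladogenesis, at two
    phylogenetic scales: clade-specific (each mainland colonist's clade has its own
    carrying capacity) and island-wide (a single carrying capacity couples all
    clades). Provides an exact event-driven stochastic simulator, an ODE-based
    likelihood for island colonization and branching times that tracks the hidden
    (extinct or unsampled) species count, maximum-likelihood fitting of five model
    variants, parametric-bootstrap likelihood-ratio model selection, and
    goodness-of-fit summaries, together with readers and writers for island
    community datasets (JSON, tab-separated colonization tables, Newick trees).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    deSolve,
    jsonlite,
    phytools,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
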