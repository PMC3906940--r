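Package: salmodiv
Title: Diploidization-Aware Paralogue Curation and Diversification
    Inference for Post-Polyploid Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating gene trees of paralogues retained from an
    ancestral whole-genome duplication (WGD) and for inferring lineage
    diversification dynamics on dated phylogenies, motivated by the salmonid
    WGD. Includes a topology classifier that screens WGD paralogue gene trees
    by their diploidization-resolution outcome, machinery to enumerate and
    sample paralogue concatenations and build orthologue supermatrices with
    codon-position partitioning, relative-rate and saturation diagnostics for
    molecular-clock screening, and first-principles diversification
    statistics: lineage-through-time curves, the gamma constant-rates test,
    constant/Weibull/breakpoint survival models of branching times, and the
    binary-state speciation-extinction (BiSSE) likelihood with maximum
    likelihood, likelihood-ratio tests and MCMC posterior summaries. A
    synthetic-data module simulates birth-death and BiSSE trees, WGD gene
    trees under alternative diploidization scenarios, HKY codon alignments
    and sea-level series so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
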