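Package: archpp
Title: Architecture Plasticity Potential of Protein Domain Superfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the capacity of protein domain superfamilies -- singly
    or grouped into functionally annotated domain sets -- to occur in distinct
    domain architectures within extant and ancestral genomes. Builds
    superfamily-by-genome architecture count matrices from SUPERFAMILY-style
    domain assignment tables, scores each annotated domain set against a
    Monte Carlo randomization null (the PP-score) with empirical p-values and
    Benjamini-Hochberg false discovery rates, reconstructs ancestral
    architecture repertoires on a rooted binary species tree by Dollo
    parsimony, and traces score trajectories along root-to-leaf lineages.
    Includes a synthetic-data generator producing power-law architecture
    diversity, Dollo-consistent gain/loss histories, and planted high/low
    plasticity terms, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
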