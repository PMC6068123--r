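Package: islandbrains
Title: Comparative Phylogenetics of Brain Size Evolution on Oceanic Islands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether island endemic lineages evolve relatively
    larger brains in situ. Implements Bayesian phylogenetic mixed models (Gibbs
    sampling for Gaussian, binary and binomial-count responses with a
    tree-structured random effect), phylogenetic generalized least squares and
    allometric residuals, sister-taxa pairing and paired models including the
    island-rule interaction, two-step ancestral reconstruction of island living
    with transition-category contrasts, phylogenetic path analysis by
    d-separation (Fisher's C, CICc model ranking), Rao quadratic entropy diet
    breadth, vegetation-index variability summaries, and a synthetic-data
    generator (birth-death trees, island colonization histories, Brownian
    traits with a known structural-equation model) providing ground truth for
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    phytools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
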