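Package: taxdist
Title: Taxonomic Distinctness of Regional Species Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes average taxonomic distinctness (Delta+) of
    presence/absence species assemblages from a ranked Linnaean taxonomy,
    builds randomization funnels (expected value and 95% confidence limits
    of Delta+ as a function of assemblage size) and richness-preserving
    null occurrence matrices, and tests whether observed regional
    distinctness patterns deviate from random expectation using a
    tie-corrected Mann-Whitney U test and Monte-Carlo permutation tests.
    Includes a seeded synthetic-data generator producing taxonomies with
    uneven clade sizes and regional assemblages that are random,
    phylogenetically clustered, or overdispersed, so the whole pipeline is
    testable without external data. The central data container couples a
    species-by-region incidence matrix with its taxonomy as a
    SummarizedExperiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
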