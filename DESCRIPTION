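Package: onebalance
Title: Single-Balance Approximation of Compositional Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Interpretation of microbiome and other compositional data
    shifts by their nearest balance: the least-squares approximation of an
    arbitrary log-ratio shift by a change in a single balance between two
    groups of parts. Provides the nearest-balance search, the best second
    balance orthogonal to a given one, greedy construction of a full
    nearest-balance coordinate tree (a sequential binary partition),
    single-balance linear regression with covariate adjustment, a
    nearest-balance reading of principal components, simulators for
    noise-stability and case-control experiments, and delimited-text input
    and output for count tables, contrast matrices and newick trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
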