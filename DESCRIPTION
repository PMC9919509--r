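Package: morphoscaffold
Title: Morphological Character Optimisation and Fossil Placement on
    Phylogenomic Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing discrete and continuous morphological
    character matrices on a fixed molecular scaffold topology: NEXUS and
    Newick input/output with ordered-character assumptions, exact parsimony
    optimisation (generalised Fitch, Sankoff with arbitrary step costs,
    linear parsimony for continuous characters) with full
    most-parsimonious-reconstruction state sets, rule-based diagnosis of
    unreversed synapomorphies and retained plesiomorphies for named clades,
    homoplasy indices, and backbone-constrained Bayesian placement of
    fragmentary fossil taxa under the Mkv model with discrete-gamma rate
    variation, summarised as clade-membership posterior probabilities and
    majority-rule consensus trees. Includes a seeded simulator of character
    matrices and fossil rows for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
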