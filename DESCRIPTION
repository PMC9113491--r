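Package: msasim
Title: Simulation of Multiple Sequence Alignments Along Phylogenetic Trees
Version: 0.1.0
Authors@R: person("msasim", "developers", role = c("aut", "cre"),
    email = "msasim@example.org")
Description: Simulates multiple sequence alignments by evolving sequences
    along rooted phylogenetic trees under continuous-time Markov substitution
    models (JC, K2P, HKY, GTR and user-supplied rate matrices) with
    invariant-site, discrete/continuous Gamma and free-rate site-rate
    heterogeneity, and an optional insertion-deletion process with Geometric,
    Negative Binomial, Zipfian and Lavalette length distributions. Each
    branch is evolved either by an event-based Gillespie algorithm driven by
    the instantaneous rate matrix or by sampling child states from the
    matrix exponential of the rate matrix, with an adaptive per-branch switch
    between the two based on the product of sequence length and branch
    length. Includes Yule-Harding and birth-death random tree generators,
    depth-bounded memory traversal with streaming tip output, and FASTA and
    PHYLIP writers with optional gzip compression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Matrix,
    ape,
    Rcpp,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
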