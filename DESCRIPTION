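Package: pdlrs
Title: Probabilistic Gene and Pseudogene Tree Evolution with Pseudogenization Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of extended gene families (genes together
    with pseudogenes) inside a dated species tree under a two-type linear
    birth-death process with duplication, loss and irreversible
    gene-to-pseudogene conversion, a relaxed molecular clock with
    independent gamma-distributed edge rates, and dual codon substitution
    models for gene and pseudogene sequence evolution.  Provides a dynamic
    programming algorithm for the gene-tree prior over a discretized
    species tree, Felsenstein pruning with a model switch at
    pseudogenization vertices, a Metropolis-Hastings sampler over gene
    trees, edge lengths, pseudogenization configurations and model
    parameters, posterior sampling of dated realizations, a forward
    simulator, and topological and temporal distance metrics between
    pseudogenization configurations.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
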