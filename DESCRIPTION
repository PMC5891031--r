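Package: wgdresolve
Title: Phylogenetic Models of Gene Loss After Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the resolution of whole-genome duplications (WGD) across
    multiple polyploid genomes. Builds double-conserved-synteny pillars from
    gene-order annotations by simulated annealing, fits a four-state
    continuous-time Markov model of duplicate loss with duplicate fixation and
    biased fractionation along a phylogeny, couples adjacent pillars through a
    hidden Markov model over subgenome assignment vectors, assigns every gene a
    posterior probability of parental subgenome of origin, and tests whether
    protein-protein interactions preferentially join products of the same
    subgenome. Includes a synthetic-data generator with known truth for all of
    the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
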