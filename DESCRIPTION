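Package: mitohap
Title: Mitogenome Haplogroup Classification, Parsimony Phylogenetics,
    Clock Dating and Skyline Demography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the mitogenome side of livestock matrilineal
    population genetics: reference-relative variant calling in standard
    mtDNA mutation nomenclature, motif-based haplogroup classification,
    mutation-annotated maximum parsimony trees with recurrence and
    back-mutation flagging, strict-clock maximum likelihood node dating on
    codon-position-partitioned protein-coding genes, Bayesian skyline plot
    inference by MCMC from serially sampled control-region sequences, and a
    heterochronous coalescent simulator that generates fully specified
    synthetic data sets with truth records for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Biostrings,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
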