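Package: phylogee
Title: Phylogenetic Generalized Estimating Equations for Binary
    Trait-Environment Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether the presence or absence of a gene across
    a set of organisms is associated with an environmental gradient while
    accounting for phylogenetic non-independence.  Implements binomial
    generalized estimating equations (GEE) with a working correlation
    derived from a phylogeny, a phylogenetic degrees-of-freedom correction
    for Wald tests, presence/absence calling from tabular homology-search
    hits with a complete-genome rule for calling absences, near-duplicate
    tip removal, greedy identity-threshold clustering, a metagenomic
    gene-frequency estimator normalized by single-copy core genes, and a
    seeded simulator (birth-death trees, joint environment/trait evolution
    as a continuous-time Markov chain, per-site Poisson hit counts) so the
    whole pipeline can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
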