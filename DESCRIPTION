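Package: thetaSweep
Title: Sample-Size Effects on Watterson's Theta and Tests of Neutrality
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how sample size biases site-frequency-based estimators
    of the population-scaled mutation rate and the neutrality tests built on
    them. Provides exact folded-spectrum implementations of Watterson's theta,
    nucleotide diversity, Tajima's D and Fu-Li D* (no outgroup), the
    McDonald-Kreitman table with Neutrality Index and the adaptive fraction
    alpha, a forward-in-time Wright-Fisher simulator of a two-branch human-like
    growth model with a gamma distribution of deleterious fitness effects
    (with theta-preserving population rescaling and a coalescent-expectation
    oracle), a subsampling sweep pipeline with log-log regression summaries,
    and a synthetic exome-SNV generator emulating the shape of large human
    polymorphism panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    deSolve,
    jsonlite,
    vcfR,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'popgen-stats.R'
    'wf-simulator.R'
    'coalescent-oracle.R'
    'mk-stats.R'
    'sweep-pipeline.R'
    'synthetic-exome.R'
    'io.R'
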