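Package: intronsim
Title: Simulation of Intron Evolution by Mutation-and-Deletion and
    Mutation-and-Insertion Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulators of spliceosomal intron evolution along a
    guide tree under two contrasting hypotheses: a long ancestral sequence
    shrinking by block deletion (MD) or a short ancestral sequence growing
    by block insertion (MI), both accompanied by point substitution at a
    configurable transition/transversion ratio.  Includes a builtin
    progressive aligner, Kimura two-parameter distance summaries, a
    bootstrap standard error of the overall mean distance, neighbor-joining
    tree inference, a ladder-layout topology concordance score, L16(4^5)
    orthogonal parameter screening, and the accompanying statistical layer
    (independent t tests, main-effects ANOVA, Duncan's multiple range
    test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
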