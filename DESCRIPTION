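Package: fgtails
Title: Significance Evaluation for Additive Scores on Discrete Factor Graphs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tail probabilities P(S > t) for additive scores defined over
    discrete, tree-structured factor graphs. Implements exact sum-product
    inference, a moment-semiring extension of message passing that computes
    the cumulant generating function of the score and its first two
    derivatives exactly, saddlepoint and normal tail approximations with an
    optional lattice correction, forward sampling, and saddlepoint-guided
    importance sampling (exponential tilting), including a latent-variable
    variant for statistics defined on observed margins. Ready-made model
    builders cover Poisson-binomial counts, position weight matrix motifs,
    higher-order Markov motifs via variable compounding, and phylogenetic
    conservation under the Jukes-Cantor substitution model. Exact
    enumeration and convolution oracles are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
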