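Package: bild
Title: Bayesian Integral Log-Odds Scores for Multiple Sequence Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Column substitution scores for multiple sequence alignment built by
    integrating a Dirichlet or Dirichlet-mixture prior over the multinomial
    distributions that generate alignment columns ("BILD" scores), together with
    the algorithms that use them: a Gibbs sampler for ungapped local multiple
    alignment with description-length-based width and inclusion selection, an
    iterative gapped aligner with asymmetric affine gap costs and semi-global
    (Erickson-Sellers) dynamic programming, and a profile hidden Markov model
    whose position-specific gap costs are derived from column scores. Includes
    prior diagnostics (implied background, implied pairwise substitution matrix
    and its relative entropy, mean multinomial relative entropy), readers for
    UCSC-style Dirichlet mixture files, and simulators for motif-implant and
    shuffled negative-control data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
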