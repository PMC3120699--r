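Package: coinfold
Title: Iterative Probabilistic Secondary Structure Prediction for Homologous RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates base-pairing probabilities for a set of homologous RNA
    sequences by iteratively combining each sequence's own nearest-neighbor
    thermodynamic partition function (intrinsic information) with extrinsic
    information mapped from the other sequences through pairwise alignment
    co-incidence probabilities computed by a hidden Markov model. Structures
    are predicted from the probabilities by thresholding or by maximum
    expected accuracy dynamic programming, and scored against reference
    structures with single-position slippage tolerance. Includes a seeded
    generator of synthetic RNA families with conserved consensus structure,
    readers and writers for FASTA, CT, dot-bracket and plain-text base-pair
    probability files, and exhaustive-enumeration reference implementations
    used as test oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
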