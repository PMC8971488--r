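Package: shapesearch
Title: Sequence-Agnostic Similarity Search for RNA Chemical Probing
    Reactivity Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Seed-and-extend similarity search over RNA chemical probing
    reactivity profiles (SHAPE reactivities or base-pairing probabilities).
    Query kmers are complexity-filtered by their Gini coefficient, looked up
    in a profile database by z-normalized Euclidean distance (MASS), grouped
    into co-diagonal high scoring groups, and extended with a banded
    affine-gap semi-global dynamic program over the continuous reactivity
    signal. Significance is assessed against an empirical extreme-value null
    built from block-shuffled database profiles, and matched alignments can
    be tested for a significant consensus secondary structure with a
    pluggable RNAalifold-compatible folding engine. Includes a synthetic
    planted-homology benchmark generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
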