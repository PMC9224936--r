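Package: mcoscreen
Title: Four-Criterion Screening of Putative Mn-Oxidizing Multicopper
    Oxidase Genes from MAG Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens predicted proteomes of metagenome-assembled genomes
    (MAGs) for putative Mn(II)-oxidizing multicopper oxidase (MCO) genes
    using a four-criterion rule: homology above a percent-identity
    threshold to known Mn-oxidizing genes (moxA, mcoA, mnxG), domain
    compatibility via a reference-derived position-specific scoring
    profile with a permutation null, conservation of the four
    copper-binding centres (T1, T2, T3a, T3b) transferred by global
    alignment, and co-clade placement with the assigned known gene in a
    neighbor-joining tree rooted on an outgroup. Includes affine-gap
    Smith-Waterman and Needleman-Wunsch alignment kernels, Poisson-corrected
    protein distances, a deterministic synthetic protein-family generator
    with ground truth for benchmarking, per-MAG roll-ups, and a small
    stable-isotope delta-notation utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
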