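Package: clonalrm
Title: Multilocus Sequence Typing, Clonal Complexes, and
    Recombination-to-Mutation Ratio Estimation for Endosymbiont
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how much of the short-term diversification
    of clonally inherited bacteria (such as the arthropod endosymbionts
    Wolbachia and Cardinium) is driven by homologous recombination versus
    point mutation.  Implements multilocus sequence typing (allele calling
    and sequence-type assignment from per-locus alignments), per-locus
    diversity statistics (variable sites, nucleotide diversity, maximum
    p-distance, Nei-Gojobori dN/dS), eBURST-style single-locus-variant
    clonal complex inference with founder prediction, classification of
    within-complex variant alleles into point mutations versus
    recombinational allele imports with strict and inclusive
    recombination:mutation ratio estimates, a MaxChi-style intragenic
    mosaic scan with a permutation test, and a forward simulator of clonal
    diversification with a truth log for estimator validation.  All
    user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
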