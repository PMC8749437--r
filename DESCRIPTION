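Package: cladeflow
Title: Population Differentiation and Gene Flow Between Two Bacterial Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the split of a bacterial species into two
    habitat-associated lineages from a core-genome alignment, a pan-genome
    gene matrix, sample metadata and growth phenotypes. Implements
    clade-specific SNP and gene detection, sliding-window Hudson F_ST,
    accessory-genome Jaccard distances with neighbor-joining, recombination
    r/m arithmetic and donor-origin classification of recombination tracts,
    Mantel and partial Mantel permutation tests contrasting isolation by
    distance with isolation by environment, and growth-rate estimation with
    rank-based group comparison. A two-clade forward simulator with full
    ground truth makes every stage testable without external genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
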