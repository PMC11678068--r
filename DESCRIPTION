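Package: selexpr
Title: Coevolution of Coding-Sequence and Expression Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for asking whether gene-expression divergence coevolves
    with coding-sequence divergence in plant genomes. Provides NG86 codon-level
    Ka/Ks estimation with Jukes-Cantor correction, ortholog best-pair selection
    and quality-control filters, expression abundance windowing and expression
    breadth summaries, a binned normal-approximation test for Ks distributions,
    a hitchhiking proximity test around positively selected (omega > 1) loci,
    conditional-expectation correlation smoothing, a permutation test for the
    difference between two dependent correlations, incidence-of-positive-
    selection summaries, and a fully seeded synthetic-data generator that
    emulates the joint structure of Ka/Ks, gene age (phylostratum), expression
    abundance and expression breadth so the whole pipeline can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
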