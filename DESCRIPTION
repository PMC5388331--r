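Package: plastomeR
Title: Structural Comparative Analysis of Plastid Genomes
Version: 0.1.0
Authors@R:
    person("plastomeR", "maintainers", email = "plastomer@example.org",
           role = c("aut", "cre"))
Description: Tools for structural comparative analysis of circular plastid
    genomes (plastomes): detection of the inverted-repeat pair and
    quadripartite LSC/IRa/SSC/IRb partitioning; four-way classification of a
    plastid gene as intact, putative pseudogene, truncated or deleted from
    pairwise alignment against an intact reference; inversion detection via
    signed gene-order permutations, locally collinear block decomposition
    and breakpoint localization to intergenic spacers; in-silico PCR
    screening of inversion presence/absence on circular genomes; and Fitch
    parsimony mapping of binary inversion characters on a phylogeny.
    Includes a seeded generator of annotated synthetic legume-like plastomes
    with planted inversion histories and gene-mutation spectra, so that the
    whole pipeline is testable without any sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
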