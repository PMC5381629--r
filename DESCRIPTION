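Package: ripburst
Title: Burst-Like Transposable Element Expansions Under RIP-Like Hypermutation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Intragenomic analysis of retrotransposon populations in fungal
    genomes with a RIP-like (repeat-induced point mutation) genome defense.
    Reads chromosome-labelled TE copy sequences, masks hypermutation target
    motifs, builds neighbor-joining phylogenies on Jukes-Cantor distances,
    reconstructs the ancestral element by marginal maximum likelihood, scores
    context-dependent RIP-like mutations per copy, detects burst-like
    expansions as clades of near-identical elements, and infers per-copy
    relative fitness from tree shape with the local branching index. Includes
    a forward-time Gillespie simulator of TE proliferation under RIP-like
    hypermutation with a replicative fitness penalty, providing ground truth
    for every stage of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
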