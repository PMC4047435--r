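Package: mcgeo
Title: Markov-Cluster Community Distances and Geochemical Correlates for
    Comparative Metagenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures whole-community evolutionary distance between
    metagenomes by Markov clustering (MCL) of an all-vs-all protein
    homology graph, converts cluster membership into binary Jaccard
    dissimilarities, builds neighbor-joining dendrograms and patristic
    distance matrices, and correlates community distance and three
    biodiversity metrics (genus, EC and Markov-cluster counts) with
    environmental geochemistry through Mantel permutation tests, Pearson
    correlation matrices and principal component ordination.  Includes a
    niche-based synthetic metagenome generator so the whole pipeline is
    testable without external sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
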