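Package: spongiome
Title: Analysis Pipeline for Deep-Sea Sponge Ground Microbiomes
Version: 0.1.0
Authors@R:
    person("Spongiome", "Developers", email = "spongiome@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse host-associated 16S amplicon data from
    deep-sea sponge grounds: ASV-table handling and filtering, alpha and
    beta diversity (Shannon, Faith's phylogenetic diversity, weighted
    UniFrac, Jaccard), core/variable/individual membership across sequence
    clustering thresholds, host-specific and exclusive ASV detection at
    every host taxonomic rank, adapted rarefaction (richness versus number
    of host species), depth-constrained least-cost sea distances with
    distance-decay statistics, permutation multivariate statistics (Dunn,
    PERMANOVA, Mantel, redundancy analysis, variation partitioning),
    similarity/bipartite/weighted-correlation networks, HMA/LMA status
    prediction by a random-forest classifier, and temperature-salinity
    water-mass classification. A seeded synthetic-data generator with
    ground-truth labels makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
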