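Package: wgdlens
Title: Detection and Phylogenomic Placement of Whole-Genome Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and place paleopolyploidy (whole-genome
    duplication, WGD) events from genome-scale data: node-weighted
    synonymous-distance (Ks) age distributions with kernel-density peak
    finding and bootstrap confidence intervals, NG86 pairwise Ks
    estimation from codon alignments, collinear (syntenic) block chaining
    and anchor-pair extraction, one-to-one block screening, Markov
    clustering of protein similarity graphs into gene families,
    reciprocal-best-hit orthologue inference, relative-rate and
    relative-timing comparisons from orthologue Ks distributions,
    gene-tree/species-tree duplication mapping with branch-interval
    circumscription, and classification of deep angiosperm (ANA-grade)
    topologies. A codon-level genome-evolution simulator with a single
    WGD, duplicate retention, and segment fractionation provides fully
    specified synthetic datasets with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    Biostrings,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
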