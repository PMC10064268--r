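Package: replitax
Title: Replicon Classification, Orthology and Genome Relatedness for
    Multipartite Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("replitax", "maintainers", email = "replitax@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for bacteria with multipartite
    genomes (chromosome, chromids, megaplasmids). Classifies replicons from
    GC content and strand-symmetric dinucleotide relative-abundance (Karlin)
    signatures, computes cumulative GC skew and origin-of-replication counts,
    finds bidirectional-best-hit (BBH) orthologs with coverage and e-value
    gates, maps cointegrated and translocated replicon segments, computes
    genome and proteome relatedness indices (fragment-based ANI, GBDP-style
    d4 identity, core-proteome AAI, whole-proteome AAI), identifies
    species-specific gene clusters in pan-genomes, and applies ANI / cpAAI
    thresholds for species and genus demarcation. A synthetic-genome module
    generates multipartite genomes, diverged strain pairs, cointegrants,
    translocations and group-structured gene content with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    ape,
    igraph,
    data.table,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
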