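Package: trackdist
Title: Feature Extraction, Similarity Measures and Hierarchical Clustering
    for Genomic Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters genomic tracks (point/segment annotations such as
    ChIP-seq peak calls, given as BED or GFF) by their genome-wide
    occupancy patterns. Implements three notions of track similarity:
    direct base-pair-level overlap (Jaccard index of covered positions),
    similarity of positional distribution along the genome (normalized
    coverage aggregated in genome bins), and similarity of relations to
    external reference tracks (aggregation over arbitrary position sets
    such as functional gene categories). Pairwise distances are
    precomputed into a distance matrix, so genome-length feature vectors
    are never materialized, and fed to agglomerative hierarchical
    clustering (UPGMA/single/complete) with dendrogram export (Newick),
    height- or k-based subcluster cutting, and TSV feature/distance
    matrix output. Includes a synthetic-track generator with known group
    structure for validation, and a command-line interface with
    replayable batch configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
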