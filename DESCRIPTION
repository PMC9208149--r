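Package: iscape
Title: Insertion Sequence Landscapes in Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects insertion sequence (IS) occurrences on bacterial and
    archaeal replicons from alignment hit tables (80:80 filtering, best
    E-value overlap resolution, same-family merging), builds IS-gene (IG)
    couples and their four orientation shapes, tests shape and gene-function
    over- and under-representation, detects IS hotspots, classifies syntenic
    IS-gene (sIG) sets across taxonomic ranks, computes phylum network
    metrics, and intersects IS intervals with regulatory motifs. Ships a
    synthetic-corpus generator with planted ground truth that exercises every
    pipeline stage, and a subcommand-style pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
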