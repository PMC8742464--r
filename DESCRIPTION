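Package: mitoarch
Title: Architecture Analysis of Intron-Rich Organelle Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to dissect the architecture of small circular organelle
    genomes, motivated by the intron- and repeat-rich mitochondrial genomes
    of red algae. Reads and writes annotated circular genomes in GenBank
    flat-file format, partitions every position into exon, intron, rRNA,
    tRNA and intergenic classes, detects tandem repeats with a
    consensus-scoring (ETANDEM-style) algorithm, computes windowed and
    cumulative GC skew to locate replication origin and terminus, decomposes
    genome size into its architectural components, profiles splice-site
    base frequencies around group II introns, finds duplicated and nested
    introns (twintrons) by seeded local self-alignment, and builds a
    similarity network of intron-encoded proteins. A seeded synthetic
    mitogenome generator with a planted-truth table makes every stage
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
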