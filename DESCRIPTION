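Package: tdnascape
Title: Transcription-Factor Binding and Chromatin-Domain Context of Human tRNA Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic chromatin profiling of tRNA gene (tDNA) loci: a per-locus
    census of ChIP-seq transcription-factor binding across cell lines with a
    three-group classification (broadly bound / cell-selective / unbound),
    strand-aware positional binding landscapes, log-odds position-weight-matrix
    scanning for CTCF motifs with ChIP confirmation and tRNA structural-region
    assignment, CTCF/cohesin triple-colocalization calling, and distance profiles
    of tDNAs against topologically associating domains (TADs), lamina-associated
    domains (LADs), DNase hypersensitive sites and conserved elements. Includes a
    fully seeded synthetic-data generator that plants known group structure,
    motif positions and domain-border placements so the whole pipeline can be
    validated end to end against a ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
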