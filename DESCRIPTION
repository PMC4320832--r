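Package: SpliceScape
Title: Splice-Junction Landscapes and Strain-Specific Splicing Across
    Inbred Strain Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-alignment analysis of RNA-seq splice-junction tables
    across a panel of inbred strains. Reads the tabular junction dialect
    emitted by spliced aligners, classifies splice-site motifs (GT/AG,
    GC/AG, AT/AC, non-canonical) against a genome FASTA, builds an
    annotated-junction database and gene index from a GTF, quantifies
    cross-strain junction conservation at coverage thresholds, clusters
    strains into a splicing phylogeny from pairwise shared-junction
    counts, and calls high-confidence strain-specific splicing events by
    three criteria: detection in exactly one strain, a read-coverage
    floor, and a canonical splice-site motif. Includes a synthetic
    landscape generator with ground truth so the full pipeline is
    testable without sequencing data.
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
    SummarizedExperiment,
    rtracklayer,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Transcriptomics, AlternativeSplicing, RNASeq, Annotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
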