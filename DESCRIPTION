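Package: ltsScaffold
Title: Genome Scaffolding by Robust Regression on Clustered Linking Distances
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Orders, orients and positions preliminary contigs into scaffolds
    from paired-read (PE/MP) and long-read (TGS) alignments. Contig
    orientations are assigned per connected component of a link-count
    scaffolding graph by minimising an Ising-type energy over relative
    orientation evidence; linking distances are clustered per contig pair and
    library by kernel density estimation so that multi-modal evidence (as
    arises around tandem repeats) is retained as separate observations; contig
    start coordinates are then estimated by a weighted least-trimmed-squares
    regression that automatically discards mistaken link clusters, and gap
    sizes are reported with confidence intervals. Includes an alignment-level
    simulator that generates planted genomes, contigs and links (including
    short-insert contamination and repeat-induced mis-mapping) so the whole
    pipeline can be exercised without external data, an iterative super-contig
    extension loop with overlap polishing, and a residual-based assessment
    module for existing scaffolds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Biostrings,
    Rsamtools,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
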