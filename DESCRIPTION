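Package: mafstream
Title: Streaming Processing and Analysis of Multiple Genome Alignments
Version: 0.1.0
Authors@R: person("mafstream", "developers", role = c("aut", "cre"),
    email = "mafstream@example.org")
Description: A streaming processor for whole-genome multiple alignments
    stored in the Multiple Alignment Format (MAF). Alignment blocks are
    pulled one at a time through a lazy chain of composable filters:
    species subsetting, syntenic-block merging, sliding-window alignment
    cleaning (gap, entropy, mask and quality based), feature-driven
    extraction and removal, window splitting, per-block population-genetic
    statistics (Watterson's theta, unfolded site-frequency spectrum,
    fixed/polymorphic site counts), distance-based phylogenetics (Kimura
    two-parameter distance, NJ/BioNJ/UPGMA/WPGMA) and exporters to MAF,
    Fasta/Clustal/Phylip, Newick, CSV and VCF. Pipelines are described in
    a declarative key=value option-file language and can be run from a
    command-line entry point. Includes a synthetic-data module (K80
    sequence simulation, synteny fixtures, topology mixtures) so the whole
    tool is testable without external genome alignments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
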