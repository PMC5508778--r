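Package: hicscaff
Title: Chromosome-Scale Scaffolding of Draft Assemblies with Hi-C Linkage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Orders and orients draft-assembly contigs into chromosome-scale
    scaffolds using Hi-C proximity-ligation read pairs. Implements
    mapping-quality filtering of paired alignments, detection of contig
    misassemblies from drops in per-base physical coverage (a minimum-sum
    subarray scan), restriction-site-normalized link weighting between contig
    ends, greedy construction of a begin/end scaffold graph with cycle
    removal, path-based layout extraction, and insertion of small contigs
    into seed scaffolds by exhaustive position and orientation scoring.
    Includes a seeded simulator of genomes, fragmented (optionally chimeric)
    contig sets and distance-decaying Hi-C contacts so the whole pipeline is
    testable without external data, plus FASTA/AGP/BED writers for the
    results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    GenomicAlignments,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
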