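Package: gclandscape
Title: Nucleotide Landscape, Repeat and Phylogenomic Dataset Analysis for
    Organelle Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the nucleotide landscape of organelle
    (mitochondrial and plastid) genomes and for assembling phylogenomic
    datasets from organelle genes.  Reads annotated GenBank flat files,
    partitions every genome position into region classes (protein-coding,
    structural RNA, intron, unclassified ORF, intergenic), and computes
    region-wise GC content, codon-position GC (GC1/GC2/GC3), GC skew,
    noncoding fraction and amino-acid composition.  Discovers maximal exact
    direct and inverted (palindromic) repeats within a genome and exact
    segments shared between two genomes, as observed between the
    mitochondrial and plastid genomes of GC-rich green algae.  Assembles
    concatenated amino-acid supermatrices with a taxon-occupancy gene
    selection rule and a conserved-block column filter, and implements
    root-to-tip distance ranking with fast-evolving-taxon removal on trees
    with branch lengths.  A seeded synthetic-genome generator emits
    annotated circular genomes with designed per-region GC, planted
    repeats, trees with controlled rate heterogeneity and gene-alignment
    sets with controlled taxon occupancy, together with machine-readable
    truth tables, so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    phytools,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
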