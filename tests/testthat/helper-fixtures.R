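# Fixtures built in code: a small handcrafted GenBank record exercising
# join/complement/wrap locations, and convenience record constructors.

# 100-nt circular record: a plus-strand CDS at 1..30, a two-exon CDS
# join(41..50,61..70) with its intron annotated, a minus-strand tRNA, an
# ORF-like CDS, and a gene wrapping the origin (91..10).
write_fixture_genbank <- function(path) {
  seq100 <- paste0(
    "atggctggagctggtgctgcagctgcttaa",  # 1..30   CDS sg01 (+)
    "gcgcgcgcgc",                       # 31..40
    "atggctggag",                       # 41..50  CDS sg02 exon 1
    "gttttttttc",                       # 51..60  intron
    "ctggtgctaa",                       # 61..70  CDS sg02 exon 2
    "gcatgcatgc",                       # 71..80
    "acgtacgtac",                       # 81..90
    "atggctggtt")                       # 91..100 wrap gene start
  lines <- c(
    "LOCUS       FIX001               100 bp    DNA     circular SYN 01-JAN-2026",
    "DEFINITION  handcrafted fixture.",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "     CDS             1..30",
    "                     /gene=\"sg01\"",
    "     CDS             join(41..50,61..68)",
    "                     /gene=\"sg02\"",
    "     intron          51..60",
    "                     /gene=\"sg02\"",
    "     tRNA            complement(71..80)",
    "                     /gene=\"trnA\"",
    "     CDS             complement(81..90)",
    "                     /product=\"hypothetical protein\"",
    "     rRNA            91..10",
    "                     /gene=\"rrnW\"",
    "ORIGIN",
    sprintf("%9d %s", 1, paste(substring(seq100, seq(1, 51, 10),
                                         seq(10, 60, 10)), collapse = " ")),
    sprintf("%9d %s", 61, paste(substring(seq100, seq(61, 91, 10),
                                          seq(70, 100, 10)), collapse = " ")),
    "//")
  writeLines(lines, path)
  path
}

# Minimal record with one or more CDS features from explicit coordinates.
rec_with_cds <- function(seq, exons, strand = "+", id = "T1",
                         circular = FALSE, extra_features = list()) {
  feats <- c(list(feature("protein_coding", exons, strand = strand,
                          gene_name = "g1")), extra_features)
  genome_record(id, seq, circular = circular, features = feats)
}

small_spec <- function(seed, length = 20000L, ...) {
  args <- list(length = length, n_protein = 6L, n_rrna = 2L, n_trna = 5L,
               n_orf = 1L, n_introns = 1L, protein_len_mean = 800,
               protein_len_sd = 150, rrna_lengths = c(1400L, 700L),
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(genome_spec, args)
}
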