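# GenBank / FASTA / Newick reading and BED round trips.

test_that("GenBank locations convert to 0-based half-open coordinates", {
  tf <- withr::local_tempfile(fileext = ".gb")
  write_fixture_genbank(tf)
  rec <- read_genome_record(tf)

  expect_s3_class(rec, "genome_record")
  expect_identical(rec$length, 100L)
  expect_true(rec$circular)
  expect_identical(rec$length, nchar(rec$sequence))

  kinds <- vapply(rec$features, function(f) f$kind, character(1))
  names(rec$features) <- vapply(rec$features, function(f) f$gene_name,
                                character(1))
  # simple range: 1..30 -> [0, 30) on the plus strand
  f1 <- rec$features[["sg01"]]
  expect_equal(unname(f1$exons), matrix(c(0L, 30L), ncol = 2), ignore_attr = TRUE)
  expect_identical(f1$strand, "+")
  # join semantics: join(41..50,61..68) -> exons [40,50) and [60,68)
  f2 <- rec$features[["sg02"]]
  expect_equal(nrow(f2$exons), 2L)
  expect_equal(as.vector(t(f2$exons)), c(40L, 50L, 60L, 68L))
  # complement sets the minus strand
  trna <- rec$features[[which(kinds == "tRNA")]]
  expect_identical(trna$strand, "-")
  # hypothetical-product CDS becomes an unclassified ORF
  expect_true("unclassified_orf" %in% kinds)
  # origin-wrapping 91..10 is split into [90,100) + [0,10), total 20 nt
  rrna <- rec$features[[which(kinds == "rRNA")]]
  expect_equal(as.vector(t(rrna$exons)), c(90L, 100L, 0L, 10L))
  expect_equal(sum(rrna$exons[, 2] - rrna$exons[, 1]), 20L)
})

test_that("feature_sequence rejoins wrap pieces and honours strand", {
  tf <- withr::local_tempfile(fileext = ".gb")
  write_fixture_genbank(tf)
  rec <- read_genome_record(tf)
  names(rec$features) <- vapply(rec$features, function(f) f$gene_name,
                                character(1))
  expect_identical(substr(feature_sequence(rec, rec$features[["sg01"]]), 1, 3),
                   "ATG")
  rrna <- rec$features[["rrnW"]]
  expect_identical(feature_sequence(rec, rrna),
                   paste0(substr(rec$sequence, 91, 100),
                          substr(rec$sequence, 1, 10)))
  trna <- rec$features[["trnA"]]
  expect_identical(feature_sequence(rec, trna),
                   revcomp(substr(rec$sequence, 71, 80)))
})

test_that("malformed records and bad residues are rejected with context", {
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp", "no origin here"), tf)
  expect_error(read_genome_record(tf), "ORIGIN")
  tf2 <- withr::local_tempfile(fileext = ".gb")
  writeLines("not a genbank file", tf2)
  expect_error(read_genome_record(tf2), "LOCUS")
  expect_error(genome_record("X", "ACGTZZ"), "IUPAC")
  expect_error(read_genome_record(tempfile()), "no such file")
})

test_that("FASTA input yields an annotation-free record", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">chrX test", "ACGTACGTNN"), tf)
  rec <- read_genome_record(tf)
  expect_identical(rec$id, "chrX")
  expect_identical(rec$length, 10L)
  expect_length(rec$features, 0L)
})

test_that("read_newick validates leaves and branch lengths", {
  t1 <- read_newick(text = "(A:1,B:2);")
  expect_setequal(t1$tip.label, c("A", "B"))
  expect_setequal(t1$edge.length, c(1, 2))
  t2 <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_length(t2$tip.label, 3L)
  expect_error(read_newick(text = "(A:1,B);"), "branch length")
  expect_error(read_newick(text = "(A:1,A:2);"), "duplicate")
})

test_that("region tables round-trip through BED, merging adjacent runs", {
  # randomized partitions from synthetic genomes
  for (seed in 1:5) {
    g <- generate_genome(small_spec(seed, length = 15000L,
                                    repeat_fraction = 0))
    part <- partition_genome(g$record)
    tf <- withr::local_tempfile(fileext = ".bed")
    write_region_table(part, tf)
    back <- read_region_table(tf, length = g$record$length)
    for (cls in names(part$classes)) {
      expect_identical(as.data.frame(IRanges::reduce(part$classes[[cls]])),
                       as.data.frame(back$classes[[cls]]))
    }
  }
  # split intervals of one class are merged into a single BED line
  part2 <- gclandscape:::new_region_partition("P", 100L, list(
    protein_coding = IRanges::IRanges(start = c(1L, 31L), end = c(30L, 60L)),
    structural_rna = IRanges::IRanges(),
    intron = IRanges::IRanges(),
    unclassified_orf = IRanges::IRanges(),
    intergenic = IRanges::IRanges(61L, 100L)))
  tf2 <- withr::local_tempfile(fileext = ".bed")
  write_region_table(part2, tf2)
  lines <- readLines(tf2)
  expect_length(lines, 2L)  # merged coding line + intergenic line
  expect_match(lines[1], "^P\t0\t60\tprotein_coding$")
})

test_that("writing then reading GenBank reproduces the record", {
  g <- generate_genome(small_spec(42L))
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g$record, tf)
  back <- read_genome_record(tf)
  expect_identical(back$sequence, g$record$sequence)
  expect_identical(back$circular, g$record$circular)
  sig <- function(r) sort(vapply(r$features, function(f) {
    paste(f$kind, f$strand, paste(t(f$exons), collapse = ","), sep = "|")
  }, character(1)))
  expect_identical(sig(back), sig(g$record))
})
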