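# Region partition, codon-position site sets, gene inventory.

test_that("partition assigns classes with the documented precedence", {
  s100 <- strrep("ACGT", 25)
  r1 <- rec_with_cds(s100, rbind(c(0L, 30L)))
  p1 <- partition_genome(r1)
  expect_equal(unname(class_lengths(p1)[c("protein_coding", "intergenic")]),
               c(30L, 70L))

  # CDS [0,30) overlapping tRNA [25,40): coding wins
  r2 <- rec_with_cds(s100, rbind(c(0L, 30L)), extra_features = list(
    feature("tRNA", rbind(c(25L, 40L)), gene_name = "trnX")))
  p2 <- partition_genome(r2)
  expect_equal(unname(class_lengths(p2)[c("protein_coding", "structural_rna",
                                          "intergenic")]),
               c(30L, 10L, 60L))

  # CDS exons [0,30)+[60,90) with annotated intron [30,60)
  r3 <- rec_with_cds(s100, rbind(c(0L, 30L), c(60L, 90L)),
                     extra_features = list(
                       feature("intron", rbind(c(30L, 60L)),
                               gene_name = "g1")))
  p3 <- partition_genome(r3)
  expect_equal(unname(class_lengths(p3)[c("protein_coding", "intron",
                                          "intergenic")]),
               c(60L, 30L, 10L))
})

test_that("partition is exhaustive, idempotent and order-independent", {
  set.seed(1)
  for (i in 1:200) {
    L <- sample(150:400, 1)
    n_feat <- sample(0:6, 1)
    feats <- lapply(seq_len(n_feat), function(k) {
      a <- sample.int(L - 10L, 1) - 1L
      b <- min(L, a + sample(3:60, 1))
      kind <- sample(c("protein_coding", "rRNA", "tRNA", "intron",
                       "unclassified_orf"), 1)
      ex <- rbind(c(a, b))
      if (kind == "protein_coding") {
        w <- b - a
        ex <- rbind(c(a, a + (w %/% 3L) * 3L))
        if (ex[1, 1] >= ex[1, 2]) ex <- rbind(c(a, a + 3L))
      }
      feature(kind, ex, strand = sample(c("+", "-"), 1), gene_name = "f")
    })
    rec <- suppressWarnings(
      genome_record("R", random_dna(L), features = feats))
    p <- suppressWarnings(partition_genome(rec))
    expect_identical(sum(class_lengths(p)), L)
    shuffled <- rec
    shuffled$features <- rev(rec$features)
    p2 <- suppressWarnings(partition_genome(shuffled))
    expect_identical(class_lengths(p), class_lengths(p2))
  }
})

test_that("codon phases follow translation order on both strands", {
  s <- "ATGGCTGGAC"
  r_plus <- rec_with_cds(paste0(s, strrep("A", 90)), rbind(c(0L, 9L)))
  cs <- codon_position_sites(r_plus)
  expect_equal(sort(cs$pos1), c(0L, 3L, 6L))
  expect_equal(sort(cs$pos2), c(1L, 4L, 7L))
  expect_equal(sort(cs$pos3), c(2L, 5L, 8L))
  expect_equal(cs$source_gene_count, 1L)

  r_minus <- rec_with_cds(paste0(strrep("C", 9), strrep("A", 91)),
                          rbind(c(0L, 9L)), strand = "-")
  cs2 <- codon_position_sites(r_minus)
  expect_equal(cs2$pos1, c(8L, 5L, 2L))
  expect_equal(cs2$pos2, c(7L, 4L, 1L))
  expect_equal(cs2$pos3, c(6L, 3L, 0L))
})

test_that("terminal stop codons are excluded unless requested", {
  seq <- paste0("ATGGCTGGATAA", strrep("C", 28))  # 12-nt CDS ending in TAA
  rec <- rec_with_cds(seq, rbind(c(0L, 12L)))
  cs <- codon_position_sites(rec)
  expect_length(c(cs$pos1, cs$pos2, cs$pos3), 9L)
  cs_all <- codon_position_sites(rec, include_stop = TRUE)
  expect_length(c(cs_all$pos1, cs_all$pos2, cs_all$pos3), 12L)
  # non-multiple-of-3 CDS is truncated to complete codons, with a warning
  rec2 <- suppressWarnings(rec_with_cds(paste0("ATGGCTGG", strrep("C", 22)),
                                        rbind(c(0L, 8L))))
  expect_warning(cs3 <- codon_position_sites(rec2), "divisible by 3")
  expect_length(c(cs3$pos1, cs3$pos2, cs3$pos3), 6L)
})

test_that("codon sites lie inside the protein-coding class and are disjoint", {
  g <- generate_genome(small_spec(9L))
  cs <- codon_position_sites(g$record)
  part <- partition_genome(g$record)
  coding <- part$classes$protein_coding
  all_sites <- c(cs$pos1, cs$pos2, cs$pos3)
  expect_false(anyDuplicated(all_sites) > 0)
  ir <- IRanges::IRanges(start = all_sites + 1L, width = 1L)
  ov <- IRanges::countOverlaps(ir, coding)
  expect_true(all(ov == 1L))
})

test_that("gene inventory counts genes, not ORFs or introns", {
  s <- strrep("ACGT", 100)
  feats <- list(
    feature("protein_coding", rbind(c(0L, 30L)), gene_name = "g1"),
    feature("protein_coding", rbind(c(40L, 70L)), gene_name = "g2"),
    feature("rRNA", rbind(c(80L, 120L)), gene_name = "rrnS"),
    feature("tRNA", rbind(c(130L, 150L)), gene_name = "trnM"),
    feature("tRNA", rbind(c(160L, 180L)), gene_name = "trnM"),
    feature("tRNA", rbind(c(190L, 210L)), gene_name = "trnF"))
  rec <- genome_record("G", s, features = feats)
  inv <- gene_inventory(rec)
  expect_equal(inv$n_total, 6L)
  expect_equal(inv$n_protein, 2L)
  expect_equal(inv$n_trna, 3L)  # duplicate trnM copies each count
  # adding unclassified ORFs and introns changes nothing
  rec2 <- genome_record("G", s, features = c(feats, list(
    feature("unclassified_orf", rbind(c(220L, 250L)), gene_name = "orf1"),
    feature("unclassified_orf", rbind(c(260L, 290L)), gene_name = "orf2"),
    feature("intron", rbind(c(300L, 330L)), gene_name = "g1"))))
  expect_equal(gene_inventory(rec2)$n_total, 6L)
  # dedupe collapses the trnM twins
  expect_equal(gene_inventory(rec, dedupe = TRUE)$n_total, 5L)
})

test_that("a CDS nested in an annotated intron is treated as an ORF", {
  s <- strrep("ACGT", 100)
  feats <- list(
    feature("protein_coding", rbind(c(0L, 30L), c(90L, 120L)),
            gene_name = "host"),
    feature("intron", rbind(c(30L, 90L)), gene_name = "host"),
    feature("protein_coding", rbind(c(40L, 70L)), gene_name = "g_inner"))
  rec <- genome_record("G", s, features = feats)
  p <- partition_genome(rec)
  # inner CDS positions fall to the intron class (precedence), and the
  # inventory does not count it as a gene
  expect_equal(unname(class_lengths(p)[["protein_coding"]]), 60L)
  expect_equal(unname(class_lengths(p)[["intron"]]), 60L)
  expect_equal(gene_inventory(rec)$n_total, 1L)
})
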