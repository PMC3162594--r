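# Synthetic-data generators: determinism, designed-GC recovery, planted
# repeats, occupancy truth, rate-multiplier ranking.

test_that("the same seed reproduces byte-identical outputs", {
  sp <- small_spec(5L)
  f1 <- withr::local_tempfile(fileext = ".gb")
  f2 <- withr::local_tempfile(fileext = ".gb")
  generate_genome(sp, path = f1)
  generate_genome(sp, path = f2)
  expect_identical(readLines(f1), readLines(f2))

  t1 <- generate_tree_and_alignments(n_taxa = 10L, n_genes = 5L, seed = 8L)
  t2 <- generate_tree_and_alignments(n_taxa = 10L, n_genes = 5L, seed = 8L)
  expect_identical(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  expect_identical(t1$alignments[[3]]$rows, t2$alignments[[3]]$rows)
  # the generator does not disturb the caller's RNG stream
  set.seed(123)
  a <- stats::runif(1)
  set.seed(123)
  invisible(generate_genome(small_spec(6L)))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("designed per-class GC is realized within the sampling bound", {
  sp <- genome_spec(length = 50000L, n_protein = 14L, n_rrna = 2L,
                    n_trna = 12L, n_orf = 1L, n_introns = 2L,
                    gc_intergenic = 0.56, seed = 77L)
  g <- generate_genome(sp)
  expect_equal(unname(g$truth$gc_class[["intergenic"]]), 0.56,
               tolerance = 0.01)
  expect_equal(unname(g$truth$gc_codon),
               unname(sp$gc_codon), tolerance = 0.005)
  expect_equal(unname(g$truth$gc_class[["structural_rna"]]),
               sp$gc_structural, tolerance = 0.005)
  # and the pipeline recovers the truth through GenBank round-trip
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g$record, tf)
  rec <- read_genome_record(tf)
  lr <- landscape_report(rec)
  expect_equal(lr$gc_intergenic_pct, 100 * g$truth$gc_class[["intergenic"]],
               tolerance = 1e-6)
  expect_equal(c(lr$gc1_pct, lr$gc2_pct, lr$gc3_pct),
               unname(100 * g$truth$gc_codon), tolerance = 1e-6)
  expect_equal(lr$noncoding_pct, g$truth$noncoding_pct, tolerance = 1e-9)
  expect_equal(lr$n_genes, g$truth$n_genes)
})

test_that("planted inverted repeats are reverse complements at truth coordinates", {
  g <- generate_genome(small_spec(55L, length = 30000L))
  tr <- g$truth$repeats
  inv <- tr[tr$orientation == "inverted", , drop = FALSE]
  expect_gte(nrow(inv), 1L)
  for (r in seq_len(nrow(inv))) {
    a <- substr(g$record$sequence, inv$pos_a[r] + 1L,
                inv$pos_a[r] + inv$length[r])
    b <- substr(g$record$sequence, inv$pos_b[r] + 1L,
                inv$pos_b[r] + inv$length[r])
    expect_identical(a, revcomp(b))
  }
  fwd <- tr[tr$orientation == "forward", , drop = FALSE]
  for (r in seq_len(nrow(fwd))) {
    expect_identical(
      substr(g$record$sequence, fwd$pos_a[r] + 1L,
             fwd$pos_a[r] + fwd$length[r]),
      substr(g$record$sequence, fwd$pos_b[r] + 1L,
             fwd$pos_b[r] + fwd$length[r]))
  }
})

test_that("generator output passes the module validators", {
  for (seed in c(2L, 3L)) {
    g <- generate_genome(small_spec(seed))
    expect_silent(gclandscape:::validate_genome_record(g$record))
    p <- partition_genome(g$record)
    expect_identical(sum(class_lengths(p)), g$record$length)
    expect_identical(unname(class_lengths(p)),
                     unname(g$truth$class_lengths[names(p$classes)]))
  }
})

test_that("infeasible specs are refused", {
  expect_error(generate_genome(genome_spec(length = 5000L, n_protein = 20L,
                                           seed = 1L)),
               "infeasible")
  expect_error(genome_spec(length = 1000L, repeat_length_range = c(20, 300)),
               "length/4")
  expect_error(genome_spec(gc_intergenic = 1.2), "GC targets")
})

test_that("per-gene occupancy truth drives gene selection exactly", {
  ts <- generate_tree_and_alignments(n_taxa = 15L, n_genes = 29L,
                                     occupancy = 0.7, seed = 99L)
  sel <- select_genes(ts$alignments, ts$tree$tip.label, 0.7)
  expected <- colnames(ts$truth$presence)[
    colMeans(ts$truth$presence) >= 0.7]
  expect_setequal(sel, expected)
})

test_that("a rate multiplier puts its taxon first in the ranking", {
  ts <- generate_tree_and_alignments(n_taxa = 12L, n_genes = 4L,
                                     fast_taxa = c(taxon_05 = 20),
                                     seed = 13L)
  rk <- root_to_tip_distances(ts$tree)
  expect_identical(rk$taxon[1], "taxon_05")
  expect_error(generate_tree_and_alignments(n_taxa = 3L), ">= 4")
  expect_error(generate_tree_and_alignments(fast_taxa = c(nope = 2),
                                            seed = 1L), "unknown fast taxa")
})
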