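# Gene selection, concatenation, conserved-block column filtering.

mk_gene <- function(name, taxa, width = 10L, char = "A") {
  gene_alignment(name, stats::setNames(rep(strrep(char, width),
                                           length(taxa)), taxa))
}

test_that("the 70% occupancy rule follows the arithmetic exactly", {
  taxa15 <- sprintf("t%02d", 1:15)
  g11 <- mk_gene("g11", taxa15[1:11])  # 11/15 = 0.733 -> in
  g10 <- mk_gene("g10", taxa15[1:10])  # 10/15 = 0.667 -> out
  g15 <- mk_gene("g15", taxa15)        # complete -> in at any threshold
  sel <- select_genes(list(g11, g10, g15), taxa15, 0.7)
  expect_setequal(sel, c("g11", "g15"))
  expect_setequal(select_genes(list(g15), taxa15, 1), "g15")
  # threshold monotonicity: raising the threshold never adds genes
  for (th in c(0.5, 0.7, 0.8, 1)) {
    expect_true(all(select_genes(list(g11, g10, g15), taxa15, th) %in%
                      select_genes(list(g11, g10, g15), taxa15, 0.5)))
  }
  expect_error(select_genes(list(g11), character(0)), "empty")
  expect_error(select_genes(list(g11), taxa15, 0), "threshold")
})

test_that("concatenation pads missing taxa with all-gap blocks", {
  a1 <- gene_alignment("g1", c(A = "MKLVV", B = "MKLVI", C = "MKIVV"))
  a2 <- gene_alignment("g2", c(A = "WWWWWWW", B = "WWWWWWW"))
  sm <- concatenate_alignments(list(a1, a2), c("A", "B", "C"))
  expect_equal(sm$width, 12L)
  expect_identical(sm$rows[3], "MKIVV-------")
  expect_equal(sm$gene_boundaries$start, c(1L, 6L))
  expect_equal(sm$gene_boundaries$end, c(5L, 12L))
  expect_equal(sm$occupancy, c(1, 1, 5 / 12))
  # single gene: the supermatrix is the alignment itself
  sm1 <- concatenate_alignments(list(a1), c("A", "B", "C"))
  expect_identical(sm1$rows, unname(c("MKLVV", "MKLVI", "MKIVV")))
  expect_error(gene_alignment("bad", c(A = "MK", A = "ML")), "duplicate")
})

test_that("column filter drops gapped columns and short blocks", {
  # fully conserved gapless matrix is unchanged
  rows <- stats::setNames(rep(strrep("ACDEFGHIKLMNPQRSTVWY", 1), 3),
                          c("A", "B", "C"))
  sm <- concatenate_alignments(list(gene_alignment("g", rows)),
                               c("A", "B", "C"))
  expect_equal(filter_columns(sm)$width, 20L)

  # a gapped column is always removed (allow_gaps = FALSE) and a 7-column
  # candidate block between gapped columns is dropped (min_block = 8)
  r2 <- c(A = "AAAAAAAA-AAAAAAA", B = "AAAAAAAA-AAAAAAA",
          C = "AAAAAAAACAAAAAAA")
  f2 <- filter_columns(concatenate_alignments(
    list(gene_alignment("g", r2)), c("A", "B", "C")))
  expect_equal(f2$width, 8L)
  expect_equal(f2$kept_columns, 1:8)
  expect_false(any(grepl("-", f2$rows, fixed = TRUE)))

  # a run of more than max_noncon non-conserved columns breaks a block
  w <- 30L
  base <- strrep("A", w)
  v1 <- paste0(strrep("A", 10), strrep("C", 11), strrep("A", 9))
  v2 <- paste0(strrep("A", 10), strrep("D", 11), strrep("A", 9))
  sm3 <- concatenate_alignments(list(gene_alignment(
    "g", c(A = base, B = v1, C = v2))), c("A", "B", "C"))
  f3 <- filter_columns(sm3, max_noncon = 10L, min_block = 8L)
  expect_equal(sort(f3$kept_columns), c(1:10, 22:30))
  # with a longer allowance the matrix survives whole
  f3b <- filter_columns(sm3, max_noncon = 11L, min_block = 8L)
  expect_equal(f3b$width, 30L)
})

test_that("column filtering is idempotent and remaps gene boundaries", {
  set.seed(4)
  ts <- generate_tree_and_alignments(n_taxa = 8L, n_genes = 6L,
                                     occupancy = 0.9, seed = 5L)
  sel <- select_genes(ts$alignments, ts$tree$tip.label, 0.7)
  keep <- Filter(function(a) a$gene_name %in% sel, ts$alignments)
  sm <- concatenate_alignments(keep, ts$tree$tip.label)
  f1 <- filter_columns(sm)
  f2 <- filter_columns(f1)
  expect_identical(f1$rows, f2$rows)
  expect_identical(f2$width, f1$width)
  # boundaries: per-gene kept widths sum to the filtered width
  gb <- f1$gene_boundaries
  widths <- ifelse(is.na(gb$start), 0L, gb$end - gb$start + 1L)
  expect_equal(sum(widths), f1$width)
  # kept columns are a subsequence of the original columns
  expect_true(all(diff(f1$kept_columns) > 0))
})

test_that("occupancy report and phylip output are well formed", {
  a1 <- gene_alignment("g1", c(A = "MKLVV", B = "MKLVI"))
  sm <- concatenate_alignments(list(a1), c("A", "B"))
  tf <- withr::local_tempfile(fileext = ".phy")
  write_phylip(sm, tf)
  lines <- readLines(tf)
  expect_identical(lines[1], "2 5")
  expect_match(lines[2], "^A  MKLVV$")
  df <- occupancy_report(sm)
  expect_equal(df$occupancy, c(1, 1))
})
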