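# Maximal repeat discovery: planted constructions, brute-force oracle
# agreement, monotonicity, coverage, shared segments.

test_that("planted direct and inverted repeats are found at their coordinates", {
  # two planted ACGTACGT copies
  s <- "AAACGTACGTTTTTACGTACGTAAA"
  hits <- find_maximal_repeats(s, min_len = 8L, orientations = "forward")
  expect_identical(hit_key(hits),
                   hit_key(oracle_maximal_repeats(s, 8L, "forward")))
  expect_true(any(hits$length >= 8L))

  # a copy and its reverse complement, flanked so the pair is exact
  set.seed(7)
  block <- random_dna(40)
  s2 <- paste0(random_dna(199), "A", block, "A", random_dna(148), "C",
               revcomp(block), "C", random_dna(199))
  hits2 <- find_maximal_repeats(s2, min_len = 40L, orientations = "inverted")
  expect_gte(nrow(hits2), 1L)
  expect_identical(hits2$orientation[1], "inverted")
  expect_equal(hits2$pos_a[1], 200L)
  expect_equal(hits2$pos_b[1], 390L)
  expect_equal(hits2$length[1], 40L)

  expect_error(find_maximal_repeats(s, min_len = 5L), ">= 8")
  expect_error(find_maximal_repeats("ACGT", min_len = 8L), "shorter")
})

test_that("hit sets equal the brute-force all-pairs oracle", {
  set.seed(11)
  for (i in 1:40) {
    alpha <- if (i %% 2) c("A", "T") else c("A", "C", "G", "T")
    n <- sample(100:700, 1)
    k <- if (length(alpha) == 2) 12L else 8L
    s <- random_dna(n, alpha)
    got <- find_maximal_repeats(s, min_len = k)
    exp <- oracle_maximal_repeats(s, k)
    expect_identical(hit_key(got), hit_key(exp))
  }
})

test_that("raising min_len never adds hits and preserves survivors", {
  set.seed(13)
  for (i in 1:10) {
    s <- random_dna(400, c("A", "T"))
    lo <- find_maximal_repeats(s, min_len = 10L)
    hi <- find_maximal_repeats(s, min_len = 14L)
    expect_lte(nrow(hi), nrow(lo))
    expect_true(all(hit_key(hi) %in% hit_key(lo)))
    expect_true(all(hi$length >= 14L))
  }
})

test_that("repeat coverage counts the union of copy intervals", {
  one <- data.frame(orientation = "forward", pos_a = 0L, pos_b = 200L,
                    length = 100L, gc_pct = 50, low_complexity = FALSE)
  expect_equal(repeat_coverage(one, 1000L), 0.2)
  two <- rbind(one, data.frame(orientation = "forward", pos_a = 50L,
                               pos_b = 500L, length = 100L, gc_pct = 50,
                               low_complexity = FALSE))
  # copies at [0,100), [50,150), [200,300), [500,600): union 350 nt
  expect_equal(repeat_coverage(two, 1000L), 0.35)
  expect_equal(repeat_coverage(one[0, ], 1000L), 0)
})

test_that("tandem low-complexity pairs are flagged, not removed", {
  s <- paste0(random_dna(100, c("C", "G")), strrep("AT", 40),
              random_dna(100, c("C", "G")))
  hits <- find_maximal_repeats(s, min_len = 20L)
  expect_gte(nrow(hits), 1L)
  expect_true(any(hits$low_complexity))
})

test_that("circular genomes report origin-spanning repeats once", {
  set.seed(17)
  s <- random_dna(3000)
  blk <- random_dna(60)
  circ <- paste0(substr(blk, 31, 60), substr(s, 31, 1470), blk,
                 substr(s, 1531, 2970), substr(blk, 1, 30))
  rec <- genome_record("CIRC", circ, circular = TRUE)
  h <- find_maximal_repeats(rec, min_len = 20L, orientations = "forward")
  expect_equal(nrow(h), 1L)
  expect_gte(h$length[1], 60L)
  # linear reading of the same sequence sees only the truncated interior
  h_lin <- find_maximal_repeats(circ, min_len = 20L,
                                orientations = "forward")
  expect_true(all(h_lin$length < 60L))
})

test_that("shared segments are exact, oriented and symmetric", {
  set.seed(19)
  block <- random_dna(100)
  # distinct flank letters in A (A...A) and B (C...C) pin down maximality
  a <- paste0(random_dna(1999), "A", block, "A", random_dna(2899))
  b <- paste0(random_dna(999), "C", block, "C", random_dna(3999))
  sh <- shared_repeats(a, b, min_len = 30L)
  expect_equal(nrow(sh$segments), 1L)
  expect_equal(sh$segments$pos_in_a, 2000L)
  expect_equal(sh$segments$pos_in_b, 1000L)
  expect_equal(sh$segments$length, 100L)
  expect_equal(sh$total_shared_nt, 100L)

  b_inv <- paste0(random_dna(999), "C", revcomp(block), "C",
                  random_dna(3999))
  sh2 <- shared_repeats(a, b_inv, min_len = 30L)
  expect_identical(sh2$segments$orientation, "inverted")
  expect_equal(sh2$segments$length, 100L)

  # symmetry: swapping the genomes swaps the roles
  sh_rev <- shared_repeats(b, a, min_len = 30L)
  expect_equal(sh_rev$segments$pos_in_a, sh$segments$pos_in_b)
  expect_equal(sh_rev$segments$pos_in_b, sh$segments$pos_in_a)
  expect_equal(sh_rev$n_sites_a, sh$n_sites_b)

  expect_error(shared_repeats(a, a), "distinct")
})

test_that("merged site counts follow the interval-merge oracle", {
  set.seed(23)
  # block bodies capped with G so deliberate A/C flank letters never match
  blocks <- replicate(6, paste0("G", random_dna(58), "G"))
  # A: blocks 2 and 3 abut (one merged site); B: each block once
  a_parts <- character(0)
  starts_a <- integer(0)
  cursor <- 0L
  for (i in seq_along(blocks)) {
    pre <- if (i == 3) "" else paste0(random_dna(200), "A")
    a_parts <- c(a_parts, pre, blocks[i], if (i == 2) "" else "A")
    starts_a <- c(starts_a, cursor + nchar(pre))
    cursor <- cursor + nchar(pre) + 60L + if (i == 2) 0L else 1L
  }
  a <- paste0(paste(a_parts, collapse = ""), random_dna(500))
  b <- paste(unlist(lapply(blocks, function(x) {
    paste0("C", x, "C", random_dna(150))
  })), collapse = "")
  sh <- shared_repeats(a, b, min_len = 30L)
  ir <- IRanges::reduce(IRanges::IRanges(start = starts_a + 1L, width = 60L))
  expect_equal(length(ir), 5L)  # blocks 2+3 merge into one site
  expect_equal(sh$n_sites_a, length(ir))
  expect_equal(sh$n_sites_b, 6L)
  expect_equal(sh$total_shared_nt, sum(IRanges::width(ir)))
})
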