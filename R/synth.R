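# Seeded synthetic-data generators: annotated circular genomes with
# designed per-region GC and planted repeats, genome pairs with shared
# repeat blocks, and trees plus gene-alignment sets with controlled
# occupancy and rate heterogeneity.  Every generator call uses one
# seed-determined pseudo-random stream (withr::with_seed) and emits a
# machine-readable truth table.
#
# Per-class GC is hit by exact-count calibrated sampling: repeat
# placements and other fixed bases are planned first, and the background
# of each class then receives exactly round(N_class * target) - fixed GC
# bases, so the realized class GC equals the designed target up to
# rounding even though planted repeats are GC-rich.

#' Specification for one synthetic organelle genome
#'
#' Defaults emulate a GC-rich algal mitochondrial genome: 65.4 kb,
#' circular, 59 genes (26 protein + 3 rRNA + 30 tRNA), a handful of
#' introns including one intronic ORF, codon-position GC
#' (GC1, GC2, GC3) = (51.4, 40.8, 59.8)%, structural-RNA GC 52.5%,
#' intergenic GC 55.7%, and GC-rich (65%) repeats covering 7% of the
#' genome with lengths 20-250 nt averaging ~100 nt.
#'
#' @param id Record identifier.
#' @param length Genome length in nt.
#' @param circular Topology flag.
#' @param n_protein,n_rrna,n_trna,n_orf Feature counts (ORFs are
#'   free-standing unclassified ORFs).
#' @param n_introns Number of introns, distributed among protein genes.
#' @param intronic_orf Plant one ORF inside the first intron.
#' @param gc_codon Named vector `c(gc1=, gc2=, gc3=)` of codon-position
#'   GC targets for protein genes (fractions).
#' @param gc_structural,gc_intron,gc_intergenic GC targets per region
#'   class (fractions in (0,1)).
#' @param gc_repeat GC target of planted repeat elements.
#' @param repeat_fraction Fraction of the genome covered by repeat
#'   copies (0 disables planting).
#' @param repeat_length_range,repeat_length_mean Repeat length law
#'   (clipped gamma).
#' @param repeat_inverted_prop Proportion of inverted (palindromic)
#'   repeat pairs.
#' @param protein_len_mean,protein_len_sd Protein gene length law (nt).
#' @param rrna_lengths rRNA gene lengths (recycled to `n_rrna`).
#' @param trna_length tRNA gene length.
#' @param wrap_feature Rotate the finished genome so that one gene
#'   crosses the origin (exercises circular wrap splitting end to end).
#' @param seed Integer seed; same seed, same spec: identical output.
#' @return A validated `genome_spec` list.
#' @export
genome_spec <- function(id = "SYNMT01",
                        length = 65400L,
                        circular = TRUE,
                        n_protein = 26L, n_rrna = 3L, n_trna = 30L,
                        n_orf = 2L,
                        n_introns = 5L,
                        intronic_orf = TRUE,
                        gc_codon = c(gc1 = 0.514, gc2 = 0.408, gc3 = 0.598),
                        gc_structural = 0.525,
                        gc_intron = 0.55,
                        gc_intergenic = 0.557,
                        gc_repeat = 0.65,
                        repeat_fraction = 0.07,
                        repeat_length_range = c(20L, 250L),
                        repeat_length_mean = 100,
                        repeat_inverted_prop = 0.4,
                        protein_len_mean = 950,
                        protein_len_sd = 250,
                        rrna_lengths = c(2800L, 1500L, 120L),
                        trna_length = 75L,
                        wrap_feature = FALSE,
                        seed = 1L) {
  spec <- list(id = id, length = as.integer(length), circular = circular,
               n_protein = n_protein, n_rrna = n_rrna, n_trna = n_trna,
               n_orf = n_orf, n_introns = n_introns,
               intronic_orf = intronic_orf,
               gc_codon = gc_codon, gc_structural = gc_structural,
               gc_intron = gc_intron, gc_intergenic = gc_intergenic,
               gc_repeat = gc_repeat, repeat_fraction = repeat_fraction,
               repeat_length_range = as.integer(repeat_length_range),
               repeat_length_mean = repeat_length_mean,
               repeat_inverted_prop = repeat_inverted_prop,
               protein_len_mean = protein_len_mean,
               protein_len_sd = protein_len_sd,
               rrna_lengths = as.integer(rrna_lengths),
               trna_length = as.integer(trna_length),
               wrap_feature = wrap_feature,
               seed = as.integer(seed))
  gcs <- c(spec$gc_codon, spec$gc_structural, spec$gc_intron,
           spec$gc_intergenic, spec$gc_repeat)
  if (any(gcs <= 0 | gcs >= 1)) stop("GC targets must be in (0, 1)",
                                     call. = FALSE)
  if (max(spec$repeat_length_range) > spec$length / 4) {
    stop("planted repeat lengths must be <= length/4", call. = FALSE)
  }
  structure(spec, class = "genome_spec")
}

#' Spec emulating a large GC-rich plastid genome
#'
#' 175.7 kb, 115 genes, codon GC (56.1, 43.6, 50.1)%, intergenic 51%.
#'
#' @param id Record identifier.
#' @param seed Integer seed.
#' @param ... Overrides passed to [genome_spec()].
#' @return A `genome_spec`.
#' @export
ptdna_like_spec <- function(id = "SYNPT01", seed = 1L, ...) {
  genome_spec(id = id, length = 175700L,
              n_protein = 81L, n_rrna = 3L, n_trna = 31L,
              n_orf = 3L, n_introns = 1L, intronic_orf = FALSE,
              gc_codon = c(gc1 = 0.561, gc2 = 0.436, gc3 = 0.501),
              gc_structural = 0.52, gc_intron = 0.50,
              gc_intergenic = 0.51,
              rrna_lengths = c(2900L, 1500L, 120L),
              protein_len_mean = 870, protein_len_sd = 230,
              seed = seed, ...)
}

# -- internal helpers -------------------------------------------------------

# n characters with exactly n_gc of them G/C (uniform within GC and AT).
exact_gc_chars <- function(n, n_gc) {
  n_gc <- max(0L, min(n, as.integer(round(n_gc))))
  is_gc <- logical(n)
  if (n_gc > 0L) is_gc[sample.int(n, n_gc)] <- TRUE
  out <- character(n)
  out[is_gc] <- sample(c("G", "C"), sum(is_gc), replace = TRUE)
  out[!is_gc] <- sample(c("A", "T"), sum(!is_gc), replace = TRUE)
  out
}

# Repair internal stop codons by swapping third-position letters between
# codons; preserves per-position letter counts exactly.
repair_stops <- function(p1, p2, p3) {
  is_stop <- function(a, b, c_) {
    a == "T" & ((b == "A" & c_ %in% c("A", "G")) | (b == "G" & c_ == "A"))
  }
  safe <- !(p1 == "T" & p2 %in% c("A", "G"))
  bad <- which(is_stop(p1, p2, p3))
  for (b in bad) {
    need <- if (p2[b] == "A") c("C", "T") else c("C", "G", "T")
    q <- which(safe & p3 %in% need)
    q <- q[q != b]
    if (!length(q)) {  # essentially unreachable for realistic pools
      p3[b] <- "C"
      next
    }
    q <- q[1]
    tmp <- p3[b]
    p3[b] <- p3[q]
    p3[q] <- tmp
  }
  p3
}

# Draw repeat pair lengths (clipped gamma, mean ~ repeat_length_mean)
# until the copies cover the requested number of nucleotides.
draw_repeat_lengths <- function(target_nt, rng, mean_len) {
  lens <- integer(0)
  while (sum(lens) * 2L < target_nt) {
    l <- round(stats::rgamma(1, shape = 4, scale = mean_len / 4))
    lens <- c(lens, as.integer(min(max(l, rng[1]), rng[2])))
  }
  lens
}

# Allocate a copy of width len (plus 1-nt flanks) inside the free
# intergenic windows; returns the 0-based start and the updated windows.
alloc_window <- function(windows, len) {
  ok <- which(windows$end - windows$start >= len + 2L)
  if (!length(ok)) return(NULL)
  w <- ok[sample.int(length(ok), 1L)]
  lo <- windows$start[w] + 1L
  hi <- windows$end[w] - 1L - len
  s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
  left <- data.frame(start = windows$start[w], end = s - 1L)
  right <- data.frame(start = s + len + 1L, end = windows$end[w])
  windows <- rbind(windows[-w, , drop = FALSE],
                   left[left$end - left$start >= 25L, , drop = FALSE],
                   right[right$end - right$start >= 25L, , drop = FALSE])
  list(start = s, windows = windows)
}

DNA4 <- c("A", "C", "G", "T")

#' Generate a synthetic annotated organelle genome
#'
#' Emits an annotated circular genome honouring the spec's region
#' layout and GC targets, with repeats planted by copy-paste (reverse
#' complement for inverted pairs) and flanking bases set so that every
#' planted pair is exactly maximal.  The accompanying truth table
#' records realized per-class GC, codon-position GC, planted repeat
#' coordinates and orientations, the gene inventory and the noncoding
#' fraction -- everything the analysis pipeline is expected to recover.
#'
#' @param spec A [genome_spec()].
#' @param path Optional GenBank output path.
#' @param planted Optional list of externally prescribed repeat copies
#'   (used by [generate_genome_pair()] to share blocks across genomes);
#'   each element is `list(block, chars, orient, lflank, rflank)`.
#' @return List with `record` (a [genome_record()]) and `truth`.
#' @export
generate_genome <- function(spec, path = NULL, planted = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  res <- withr::with_seed(spec$seed, generate_genome_impl(spec, planted))
  if (!is.null(path)) write_genbank(res$record, path)
  res
}

generate_genome_impl <- function(spec, planted = NULL) {
  L <- spec$length

  ## -- 1. plan gene structures --------------------------------------------
  codons <- pmax(60L, as.integer(round(stats::rnorm(
    spec$n_protein, spec$protein_len_mean / 3, spec$protein_len_sd / 3))))
  rrna_len <- rep_len(spec$rrna_lengths, spec$n_rrna)
  orf_codons <- if (spec$n_orf > 0L) {
    sample(60:150, spec$n_orf, replace = TRUE)
  } else integer(0)
  intron_genes <- if (spec$n_introns > 0L) {
    sample.int(spec$n_protein, min(spec$n_introns, spec$n_protein))
  } else integer(0)
  intron_len <- stats::setNames(
    sample(250:600, length(intron_genes), replace = TRUE), intron_genes)
  iorf_codons <- 0L
  if (spec$intronic_orf && length(intron_genes)) {
    iorf_codons <- sample(60:120, 1L)
    intron_len[1] <- 3L * iorf_codons + 60L  # 30-nt pads around the ORF
  }

  elements <- c(
    lapply(seq_len(spec$n_protein), function(i) {
      iv <- unname(intron_len[as.character(i)])
      list(type = "protein", idx = i, nt = 3L * codons[i],
           intron = if (length(iv) && !is.na(iv)) iv else 0L,
           iorf = if (length(intron_genes) && i == intron_genes[1] &&
                        iorf_codons > 0L) 3L * iorf_codons else 0L)
    }),
    lapply(seq_len(spec$n_rrna), function(i) {
      list(type = "rrna", idx = i, nt = rrna_len[i], intron = 0L, iorf = 0L)
    }),
    lapply(seq_len(spec$n_trna), function(i) {
      list(type = "trna", idx = i, nt = spec$trna_length, intron = 0L,
           iorf = 0L)
    }),
    lapply(seq_len(spec$n_orf), function(i) {
      list(type = "orf", idx = i, nt = 3L * orf_codons[i], intron = 0L,
           iorf = 0L)
    }))
  elements <- elements[sample.int(length(elements))]
  total_nt <- sum(vapply(elements, function(e) e$nt + e$intron, integer(1)))
  n_el <- length(elements)
  min_gap <- 40L
  if (total_nt + n_el * min_gap + 200L > L) {
    stop("infeasible spec: features exceed the genome length", call. = FALSE)
  }

  ## -- 2. lay out intervals ------------------------------------------------
  free_nt <- L - total_nt - 150L  # keep a margin after the last feature
  props <- stats::rexp(n_el) + 0.2
  gaps <- pmax(min_gap, as.integer(floor(free_nt * props / sum(props))))
  while (sum(gaps) > free_nt) {
    w <- which.max(gaps)
    gaps[w] <- max(min_gap, gaps[w] - (sum(gaps) - free_nt))
    if (all(gaps == min_gap)) break
  }

  cursor <- 0L
  genes <- list()       # protein genes: strand, exons, codons, kind
  feats <- list()       # genome_record features
  cls <- list(protein_coding = list(), structural_rna = list(),
              intron = list(), unclassified_orf = list(),
              intergenic = list())
  gname_i <- c(protein = 0L, rrna = 0L, trna = 0L, orf = 0L)
  add_cls <- function(class, s, e) {
    cls[[class]][[length(cls[[class]]) + 1L]] <<- c(s, e)
  }

  for (k in seq_len(n_el)) {
    el <- elements[[k]]
    cursor <- cursor + gaps[k]
    s <- cursor
    strand <- sample(c("+", "-"), 1L)
    if (el$type == "protein") {
      gname_i["protein"] <- gname_i["protein"] + 1L
      nm <- sprintf("sg%02d", gname_i["protein"])
      if (el$intron > 0L) {
        split_at <- 3L * sample.int(el$nt %/% 3L - 2L, 1L)
        ex <- rbind(c(s, s + split_at),
                    c(s + split_at + el$intron, s + el$nt + el$intron))
        add_cls("protein_coding", ex[1, 1], ex[1, 2])
        add_cls("protein_coding", ex[2, 1], ex[2, 2])
        istart <- s + split_at
        iend <- istart + el$intron
        add_cls("intron", istart, iend)
        feats[[length(feats) + 1L]] <- feature(
          "intron", rbind(c(istart, iend)), strand = strand,
          gene_name = nm)
        if (el$iorf > 0L) {
          os <- istart + 30L
          oe <- os + el$iorf
          gname_i["orf"] <- gname_i["orf"] + 1L
          onm <- sprintf("orf%03d", gname_i["orf"])
          feats[[length(feats) + 1L]] <- feature(
            "unclassified_orf", rbind(c(os, oe)), strand = "+",
            gene_name = onm)
          genes[[length(genes) + 1L]] <- list(
            kind = "iorf", strand = "+", exons = rbind(c(os, oe)),
            codons = el$iorf %/% 3L, name = onm)
        }
      } else {
        ex <- rbind(c(s, s + el$nt))
        add_cls("protein_coding", ex[1, 1], ex[1, 2])
      }
      feats[[length(feats) + 1L]] <- feature("protein_coding", ex,
                                             strand = strand, gene_name = nm)
      genes[[length(genes) + 1L]] <- list(kind = "protein", strand = strand,
                                          exons = ex, codons = el$nt %/% 3L,
                                          name = nm)
      cursor <- s + el$nt + el$intron
    } else if (el$type %in% c("rrna", "trna")) {
      gname_i[el$type] <- gname_i[el$type] + 1L
      nm <- if (el$type == "rrna") sprintf("rrn%d", gname_i["rrna"]) else
        sprintf("trn%02d", gname_i["trna"])
      feats[[length(feats) + 1L]] <- feature(
        ifelse(el$type == "rrna", "rRNA", "tRNA"), rbind(c(s, s + el$nt)),
        strand = strand, gene_name = nm)
      add_cls("structural_rna", s, s + el$nt)
      cursor <- s + el$nt
    } else {  # free-standing unclassified ORF
      gname_i["orf"] <- gname_i["orf"] + 1L
      nm <- sprintf("orf%03d", gname_i["orf"])
      feats[[length(feats) + 1L]] <- feature(
        "unclassified_orf", rbind(c(s, s + el$nt)), strand = strand,
        gene_name = nm)
      add_cls("unclassified_orf", s, s + el$nt)
      genes[[length(genes) + 1L]] <- list(kind = "orf", strand = strand,
                                          exons = rbind(c(s, s + el$nt)),
                                          codons = el$nt %/% 3L, name = nm)
      cursor <- s + el$nt
    }
  }

  to_mat <- function(lst) {
    if (!length(lst)) return(matrix(integer(0), ncol = 2L))
    do.call(rbind, lst)
  }
  cls_mat <- lapply(cls, to_mat)
  occupied <- rbind(cls_mat$protein_coding, cls_mat$structural_rna,
                    cls_mat$intron, cls_mat$unclassified_orf)
  occ_ir <- IRanges::reduce(ir_from0(occupied[, 1], occupied[, 2]))
  inter_ir <- IRanges::setdiff(IRanges::IRanges(1L, L), occ_ir)

  ## -- 3. plan repeats in intergenic windows ------------------------------
  windows <- data.frame(start = IRanges::start(inter_ir) - 1L,
                        end = IRanges::end(inter_ir))
  copies <- list()  # block, start, len, orient(+/-), lflank, rflank, chars
  blocks <- list()
  place_copy <- function(block_id, chars, orient, lflank, rflank) {
    a <- alloc_window(windows, length(chars))
    if (is.null(a)) return(FALSE)
    windows <<- a$windows
    copies[[length(copies) + 1L]] <<- list(
      block = block_id, start = a$start, len = length(chars),
      orient = orient, lflank = lflank, rflank = rflank, chars = chars)
    TRUE
  }
  for (pc in planted %||% list()) {
    if (!place_copy(pc$block, pc$chars, pc$orient, pc$lflank, pc$rflank)) {
      stop("could not place a prescribed shared block; spec too dense",
           call. = FALSE)
    }
  }
  if (spec$repeat_fraction > 0) {
    lens <- draw_repeat_lengths(spec$repeat_fraction * L,
                                spec$repeat_length_range,
                                spec$repeat_length_mean)
    for (b in seq_along(lens)) {
      id <- sprintf("%s_rep%03d", spec$id, b)
      chars <- exact_gc_chars(lens[b], lens[b] * spec$gc_repeat)
      inverted <- stats::runif(1) < spec$repeat_inverted_prop
      lfl <- sample(DNA4, 2L)
      rfl <- sample(DNA4, 2L)
      ok1 <- place_copy(id, chars, "+", lfl[1], rfl[1])
      ok2 <- ok1 && place_copy(id, chars, if (inverted) "-" else "+",
                               lfl[2], rfl[2])
      if (!ok2) break  # intergenic space exhausted
      blocks[[id]] <- chars
    }
  }

  ## -- 4. synthesise the sequence (exact-count GC calibration) ------------
  z <- character(L)

  # Protein + ORF codon pools share the codon-position GC targets.
  pgenes <- Filter(function(g) g$kind == "protein", genes)
  other_cds <- Filter(function(g) g$kind != "protein", genes)
  fill_cds_pool <- function(gset, gc123) {
    if (!length(gset)) return(invisible())
    n_int <- vapply(gset, function(g) g$codons - 2L, integer(1))
    N_int <- sum(n_int)
    n_g <- length(gset)
    N_meas <- N_int + n_g  # internal codons + the fixed ATG starts
    p1 <- exact_gc_chars(N_int, N_meas * gc123[["gc1"]])
    p2 <- exact_gc_chars(N_int, N_meas * gc123[["gc2"]])
    p3 <- exact_gc_chars(N_int, N_meas * gc123[["gc3"]] - n_g)
    p3 <- repair_stops(p1, p2, p3)
    offs <- cumsum(c(0L, n_int))
    for (gi in seq_along(gset)) {
      g <- gset[[gi]]
      idx <- if (n_int[gi] > 0L) (offs[gi] + 1L):(offs[gi] + n_int[gi]) else
        integer(0)
      stream <- c("A", "T", "G",
                  as.vector(rbind(p1[idx], p2[idx], p3[idx])),
                  seq_chars(sample(c("TAA", "TAG", "TGA"), 1L)))
      pos <- feature_positions(
        feature("protein_coding", g$exons, strand = g$strand))
      if (g$strand == "-") {
        z[pos + 1L] <<- comp_chars(stream)
      } else {
        z[pos + 1L] <<- stream
      }
    }
    invisible()
  }
  fill_cds_pool(pgenes, spec$gc_codon)
  fill_cds_pool(other_cds, spec$gc_codon)

  fill_class <- function(mat, target) {
    if (!nrow(mat)) return(invisible())
    idx <- unlist(lapply(seq_len(nrow(mat)), function(i) {
      seq.int(mat[i, 1] + 1L, mat[i, 2])
    }), use.names = FALSE)
    idx <- idx[z[idx] == ""]  # only unfilled background
    n_tot <- sum(mat[, 2] - mat[, 1])
    fixed_gc <- sum(z[setdiff(unlist(lapply(seq_len(nrow(mat)), function(i) {
      seq.int(mat[i, 1] + 1L, mat[i, 2])
    })), idx)] %in% c("G", "C"))
    z[idx] <<- exact_gc_chars(length(idx), n_tot * target - fixed_gc)
    invisible()
  }
  fill_class(cls_mat$structural_rna, spec$gc_structural)
  fill_class(cls_mat$intron, spec$gc_intron)  # intronic ORF already placed

  # Repeat copies and their fixed flanks, then calibrated intergenic fill.
  for (cp in copies) {
    body <- if (cp$orient == "+") cp$chars else rev(comp_chars(cp$chars))
    z[(cp$start + 1L):(cp$start + cp$len)] <- body
    if (cp$orient == "+") {
      z[cp$start] <- cp$lflank                       # 0-based start-1
      z[cp$start + cp$len + 1L] <- cp$rflank
    } else {
      z[cp$start + cp$len + 1L] <- comp_chars(cp$lflank)
      z[cp$start] <- comp_chars(cp$rflank)
    }
  }
  inter_mat <- cbind(IRanges::start(inter_ir) - 1L, IRanges::end(inter_ir))
  fill_class(inter_mat, spec$gc_intergenic)

  ## -- 5. assemble record + truth -----------------------------------------
  record <- genome_record(spec$id, paste(z, collapse = ""),
                          circular = spec$circular, features = feats)
  rotation <- 0L
  if (spec$wrap_feature) {
    g1 <- pgenes[[1]]
    rotation <- as.integer((min(g1$exons) + max(g1$exons)) %/% 2)
    record <- rotate_record(record, rotation)
  }
  rot <- function(p) (p - rotation) %% L

  pair_rows <- list()
  by_block <- split(seq_along(copies), vapply(copies, function(c_) c_$block,
                                              character(1)))
  for (bid in names(by_block)) {
    ix <- by_block[[bid]]
    if (length(ix) < 2L) next
    for (u in seq_along(ix)) {
      for (v in seq_along(ix)) {
        if (u >= v) next
        c1 <- copies[[ix[u]]]
        c2 <- copies[[ix[v]]]
        a <- rot(c1$start)
        b <- rot(c2$start)
        if (a > b) { tmp <- a; a <- b; b <- tmp }
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          block = bid,
          orientation = if (c1$orient == c2$orient) "forward" else "inverted",
          pos_a = a, pos_b = b, length = c1$len, stringsAsFactors = FALSE)
      }
    }
  }
  repeats_truth <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(block = character(0), orientation = character(0),
               pos_a = integer(0), pos_b = integer(0), length = integer(0))

  zc <- seq_chars(record$sequence)
  gc_of_mat <- function(mat) {
    if (!nrow(mat)) return(NA_real_)
    idx <- unlist(lapply(seq_len(nrow(mat)), function(i) {
      rot(seq.int(mat[i, 1], mat[i, 2] - 1L)) + 1L
    }), use.names = FALSE)
    gc_fraction(zc[idx])
  }
  codon_truth <- local({
    sets <- list(pos1 = integer(0), pos2 = integer(0), pos3 = integer(0))
    for (g in pgenes) {
      pos <- feature_positions(
        feature("protein_coding", g$exons, strand = g$strand))
      pos <- pos[seq_len(3L * (g$codons - 1L))]  # drop the terminal stop
      ph <- rep.int(1:3, g$codons - 1L)
      sets$pos1 <- c(sets$pos1, pos[ph == 1L])
      sets$pos2 <- c(sets$pos2, pos[ph == 2L])
      sets$pos3 <- c(sets$pos3, pos[ph == 3L])
    }
    c(gc1 = gc_fraction(zc[rot(sets$pos1) + 1L]),
      gc2 = gc_fraction(zc[rot(sets$pos2) + 1L]),
      gc3 = gc_fraction(zc[rot(sets$pos3) + 1L]))
  })
  inter_mat0 <- cbind(IRanges::start(inter_ir) - 1L, IRanges::end(inter_ir))
  len_coding <- sum(cls_mat$protein_coding[, 2] - cls_mat$protein_coding[, 1])
  len_struct <- sum(cls_mat$structural_rna[, 2] - cls_mat$structural_rna[, 1])
  # Coverage truth counts only copies with a within-genome partner;
  # single copies of cross-genome blocks are not repeats of this genome.
  paired <- unlist(lapply(by_block, function(ix) {
    if (length(ix) >= 2L) ix else integer(0)
  }), use.names = FALSE)
  copy_mat <- if (length(paired)) {
    t(vapply(copies[paired], function(c_) c(rot(c_$start), c_$len),
             integer(2)))
  } else matrix(integer(0), ncol = 2L)

  truth <- list(
    genome_id = spec$id,
    length = L,
    gc_total = gc_fraction(zc),
    gc_skew = gc_skew(zc),
    gc_class = c(
      protein_coding = gc_of_mat(cls_mat$protein_coding),
      structural_rna = gc_of_mat(cls_mat$structural_rna),
      intron = gc_of_mat(cls_mat$intron),
      unclassified_orf = gc_of_mat(cls_mat$unclassified_orf),
      intergenic = gc_of_mat(inter_mat0)),
    gc_codon = codon_truth,
    class_lengths = c(
      protein_coding = len_coding, structural_rna = len_struct,
      intron = sum(cls_mat$intron[, 2] - cls_mat$intron[, 1]),
      unclassified_orf = sum(cls_mat$unclassified_orf[, 2] -
                               cls_mat$unclassified_orf[, 1]),
      intergenic = sum(inter_mat0[, 2] - inter_mat0[, 1])),
    noncoding_pct = 100 * (1 - (len_coding + len_struct) / L),
    n_genes = spec$n_protein + spec$n_rrna + spec$n_trna,
    repeats = repeats_truth,
    repeat_coverage = if (nrow(copy_mat)) {
      sum(IRanges::width(IRanges::reduce(
        hit_ranges(copy_mat[, 1], copy_mat[, 2], L)))) / L
    } else 0,
    copies = lapply(copies, function(c_) {
      list(block = c_$block, start = rot(c_$start), len = c_$len,
           orient = c_$orient)
    }),
    seed = spec$seed)
  list(record = record, truth = truth)
}

#' Generate a genome pair sharing repeat blocks
#'
#' Plants the same repeat blocks (or their reverse complements) in two
#' genomes, emulating organelle genome pairs that carry identical
#' repeat sequence in both compartments.  `shared` controls the block
#' geometry; the default plants 5 blocks once each in genome A and
#' spreads 11 copies over genome B, for ~500 nt of shared sequence.
#'
#' @param spec_a,spec_b Two [genome_spec()]s (distinct ids).
#' @param shared `data.frame` with columns `length`, `orientation`
#'   (`"forward"`/`"inverted"`, orientation of the B copies relative to
#'   A) and `copies_in_b`.
#' @param gc_shared GC fraction of the shared blocks.
#' @return List with `record_a`, `record_b`, `truth_a`, `truth_b` and
#'   `shared_truth` (`data.frame` of cross-genome segments plus
#'   expected site counts).
#' @export
generate_genome_pair <- function(spec_a, spec_b,
                                 shared = data.frame(
                                   length = c(100L, 100L, 100L, 100L, 100L),
                                   orientation = c("forward", "forward",
                                                   "inverted", "forward",
                                                   "inverted"),
                                   copies_in_b = c(3L, 2L, 2L, 2L, 2L)),
                                 gc_shared = 0.65) {
  stopifnot(inherits(spec_a, "genome_spec"), inherits(spec_b, "genome_spec"))
  if (identical(spec_a$id, spec_b$id)) {
    stop("spec ids must differ", call. = FALSE)
  }
  if (any(shared$copies_in_b > 3L)) {
    stop("at most 3 copies of a block per genome (4 distinct flank letters)",
         call. = FALSE)
  }
  pair_seed <- spec_a$seed + 1000003L * (spec_b$seed %% 1000L)
  plan <- withr::with_seed(pair_seed, {
    lapply(seq_len(nrow(shared)), function(b) {
      n_b <- shared$copies_in_b[b]
      # Distinct flank letters per copy (in block space) across both
      # genomes guarantee each cross-pair is exactly maximal.
      lfl <- sample(DNA4, n_b + 1L)
      rfl <- sample(DNA4, n_b + 1L)
      list(id = sprintf("shared%02d", b),
           chars = exact_gc_chars(shared$length[b],
                                  shared$length[b] * gc_shared),
           orient_b = shared$orientation[b],
           lfl = lfl, rfl = rfl, n_b = n_b)
    })
  })
  planted_a <- lapply(plan, function(p) {
    list(block = p$id, chars = p$chars, orient = "+",
         lflank = p$lfl[1], rflank = p$rfl[1])
  })
  planted_b <- unlist(lapply(plan, function(p) {
    lapply(seq_len(p$n_b), function(ci) {
      list(block = p$id, chars = p$chars,
           orient = if (p$orient_b == "inverted") "-" else "+",
           lflank = p$lfl[ci + 1L], rflank = p$rfl[ci + 1L])
    })
  }), recursive = FALSE)
  A <- generate_genome(spec_a, planted = planted_a)
  B <- generate_genome(spec_b, planted = planted_b)

  seg_rows <- list()
  for (p in plan) {
    a_cp <- Filter(function(c_) c_$block == p$id, A$truth$copies)[[1]]
    b_cps <- Filter(function(c_) c_$block == p$id, B$truth$copies)
    for (bc in b_cps) {
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        block = p$id,
        orientation = if (bc$orient == a_cp$orient) "forward" else "inverted",
        pos_in_a = a_cp$start, pos_in_b = bc$start, length = a_cp$len,
        stringsAsFactors = FALSE)
    }
  }
  shared_truth <- do.call(rbind, seg_rows)
  list(record_a = A$record, record_b = B$record,
       truth_a = A$truth, truth_b = B$truth,
       shared_truth = list(
         segments = shared_truth,
         n_sites_a = nrow(shared),
         n_sites_b = sum(shared$copies_in_b),
         total_shared_nt = sum(shared$length)))
}

#' Generate a tree and gene-alignment set with controlled occupancy
#'
#' Simulates a birth-death tree, scales the pendant edges of designated
#' fast-evolving taxa, applies mild lognormal rate noise to every edge,
#' and emits per-gene amino-acid alignments in which each taxon is
#' present independently with the given occupancy probability.  The
#' alignments are presence/absence scaffolds with random residues --
#' sufficient for gene selection, concatenation and column-filter
#' logic, not a substitution-model simulation.
#'
#' @param n_taxa Number of taxa (>= 4); defaults emulate a 25-taxon,
#'   67-gene plastid-protein dataset.
#' @param n_genes Number of gene alignments.
#' @param occupancy Per-gene, per-taxon presence probability in (0, 1].
#' @param conservation Probability that an alignment column is fully
#'   conserved (all present taxa share one residue); the rest are
#'   independent random residues.  Gives block filters realistic
#'   conserved/variable structure.
#' @param fast_taxa Named numeric vector of terminal-branch rate
#'   multipliers (>= 1) relative to the average lineage, names in
#'   `taxon_01 ...` format.
#' @param seed Integer seed.
#' @param dir Optional output directory (Newick + per-gene FASTA).
#' @return List with `tree` (`phylo`), `alignments` (list of
#'   [gene_alignment()]), and `truth` (presence matrix, realized
#'   per-gene occupancy, root-to-tip distances, fast taxa).
#' @export
generate_tree_and_alignments <- function(n_taxa = 25L, n_genes = 67L,
                                         occupancy = 0.8,
                                         conservation = 0.6,
                                         fast_taxa = NULL, seed = 1L,
                                         dir = NULL) {
  if (!(conservation >= 0 && conservation <= 1)) {
    stop("conservation must be in [0, 1]", call. = FALSE)
  }
  if (n_taxa < 4L) stop("n_taxa must be >= 4", call. = FALSE)
  if (!(occupancy > 0 && occupancy <= 1)) {
    stop("occupancy must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(fast_taxa) && any(fast_taxa < 1)) {
    stop("rate multipliers must be >= 1", call. = FALSE)
  }
  out <- withr::with_seed(as.integer(seed), {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0.4)
    tree$tip.label <- sprintf("taxon_%02d", seq_len(n_taxa))
    # Mild lognormal rate noise; the sd keeps baseline root-to-tip
    # spread well below a designed multiplier of a few, so rate
    # heterogeneity stays controlled by fast_taxa.
    tree$edge.length <- tree$edge.length *
      stats::rlnorm(length(tree$edge.length), 0, 0.15)
    if (!is.null(fast_taxa)) {
      unknown <- setdiff(names(fast_taxa), tree$tip.label)
      if (length(unknown)) {
        stop("unknown fast taxa: ", paste(unknown, collapse = ", "),
             call. = FALSE)
      }
      # The multiplier is a rate relative to the average terminal
      # lineage: the pendant branch becomes multiplier x the mean
      # pendant length, so designated taxa are fast regardless of how
      # short their own pendant edge happened to be.
      pendant <- tree$edge[, 2] <= n_taxa
      mean_pendant <- mean(tree$edge.length[pendant])
      for (nm in names(fast_taxa)) {
        e <- which(tree$edge[, 2] == match(nm, tree$tip.label))
        tree$edge.length[e] <- mean_pendant * fast_taxa[[nm]]
      }
    }
    aa <- setdiff(sort(unique(Biostrings::GENETIC_CODE)), "*")
    gene_len <- sample(150:600, n_genes, replace = TRUE)
    presence <- matrix(stats::runif(n_taxa * n_genes) < occupancy,
                       nrow = n_taxa,
                       dimnames = list(tree$tip.label,
                                       sprintf("gene_%03d", seq_len(n_genes))))
    empty <- colSums(presence) == 0L
    presence[1L, empty] <- TRUE  # keep every gene non-empty
    alignments <- lapply(seq_len(n_genes), function(g) {
      taxa <- tree$tip.label[presence[, g]]
      w <- gene_len[g]
      cons_col <- stats::runif(w) < conservation
      cons_res <- sample(aa, w, replace = TRUE)
      seqs <- vapply(taxa, function(tx) {
        res <- sample(aa, w, replace = TRUE)
        res[cons_col] <- cons_res[cons_col]
        paste(res, collapse = "")
      }, character(1))
      gene_alignment(colnames(presence)[g], seqs)
    })
    list(tree = tree, alignments = alignments, presence = presence,
         gene_len = gene_len)
  })
  rtt <- ape::node.depth.edgelength(out$tree)[seq_len(n_taxa)]
  truth <- list(presence = out$presence,
                occupancy_realized = colMeans(out$presence),
                root_to_tip = stats::setNames(rtt, out$tree$tip.label),
                fast_taxa = fast_taxa, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ape::write.tree(out$tree, file.path(dir, "tree.nwk"))
    for (al in out$alignments) {
      writeLines(as.vector(rbind(paste0(">", al$taxa), al$rows)),
                 file.path(dir, paste0(al$gene_name, ".fasta")))
    }
  }
  list(tree = out$tree, alignments = out$alignments, truth = truth)
}

#' Write a generator truth table as JSON
#'
#' @param truth A `truth` list from [generate_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}
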