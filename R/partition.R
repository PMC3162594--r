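# Region partition: assign every genome position to exactly one region
# class, and derive codon-position site sets and gene inventories.

REGION_CLASSES <- c("protein_coding", "structural_rna", "intron",
                    "unclassified_orf", "intergenic")

# [start, end) 0-based half-open -> IRanges (1-based closed).
ir_from0 <- function(starts, ends) {
  keep <- ends > starts
  IRanges::IRanges(start = as.integer(starts[keep]) + 1L,
                   end = as.integer(ends[keep]))
}

exon_ranges <- function(features) {
  if (!length(features)) return(IRanges::IRanges())
  ex <- do.call(rbind, lapply(features, function(f) f$exons))
  IRanges::reduce(ir_from0(ex[, 1], ex[, 2]))
}

new_region_partition <- function(genome_id, length, classes) {
  structure(list(genome_id = genome_id, length = length, classes = classes),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  lens <- class_lengths(x)
  cat(sprintf("<region_partition> %s (%d nt)\n", x$genome_id, x$length))
  for (cls in names(lens)) {
    cat(sprintf("  %-16s %8d nt (%5.1f%%)\n", cls, lens[[cls]],
                100 * lens[[cls]] / x$length))
  }
  invisible(x)
}

#' Per-class lengths of a region partition
#'
#' @param partition A [partition_genome()] result.
#' @return Named integer vector; sums to the genome length.
#' @export
class_lengths <- function(partition) {
  vapply(partition$classes, function(ir) sum(IRanges::width(ir)), integer(1))
}

# Reclassify any CDS nested entirely within an annotated intron as an
# unclassified ORF (intronic ORFs are noncoding by the gene-inventory and
# noncoding-fraction conventions).
effective_features <- function(record) {
  intron_ir <- exon_ranges(Filter(function(f) f$kind == "intron",
                                  record$features))
  lapply(record$features, function(f) {
    if (f$kind == "protein_coding" && length(intron_ir)) {
      span <- ir_from0(min(f$exons[, 1]), max(f$exons[, 2]))
      ov <- IRanges::findOverlaps(span, intron_ir, type = "within")
      if (length(ov)) f$kind <- "unclassified_orf"
    }
    f
  })
}

#' Partition a genome into mutually exclusive region classes
#'
#' Every position of `[0, length)` is assigned to exactly one of
#' `protein_coding`, `structural_rna` (rRNA + tRNA), `intron`,
#' `unclassified_orf`, or `intergenic`.  When annotations overlap, the
#' precedence is protein_coding > structural_rna > intron >
#' unclassified_orf; intergenic is the complement of all features.  A CDS
#' nested inside an annotated intron is treated as an unclassified ORF.
#'
#' @param record A [genome_record()].
#' @param derive_introns When `TRUE` (default), gaps between consecutive
#'   exons of a multi-exon feature are classified as intron even without
#'   an explicit intron feature.
#' @return A `region_partition`; per-class lengths always sum exactly to
#'   the genome length.
#' @export
partition_genome <- function(record, derive_introns = TRUE) {
  validate_genome_record(record)
  feats <- effective_features(record)
  by_kind <- function(k) Filter(function(f) f$kind %in% k, feats)

  coding <- exon_ranges(by_kind("protein_coding"))
  structural <- exon_ranges(by_kind(c("rRNA", "tRNA")))
  intron <- exon_ranges(by_kind("intron"))
  if (derive_introns) {
    implied <- lapply(Filter(function(f) nrow(f$exons) > 1L &&
                               f$kind != "other", feats), function(f) {
      # Wrap splits ([a, L) + [0, b)) are topology, not introns.
      sp <- IRanges::setdiff(ir_from0(min(f$exons[, 1]), max(f$exons[, 2])),
                             ir_from0(f$exons[, 1], f$exons[, 2]))
      if (record$circular) {
        wrapish <- f$exons[, 1] == 0L | f$exons[, 2] == record$length
        if (all(wrapish)) sp <- IRanges::IRanges()
      }
      sp
    })
    if (length(implied)) {
      intron <- IRanges::reduce(c(intron, do.call(c, implied)))
    }
  }
  orf <- exon_ranges(by_kind("unclassified_orf"))

  structural <- IRanges::setdiff(structural, coding)
  occupied <- IRanges::union(coding, structural)
  intron <- IRanges::setdiff(intron, occupied)
  occupied <- IRanges::union(occupied, intron)
  orf <- IRanges::setdiff(orf, occupied)
  occupied <- IRanges::union(occupied, orf)
  intergenic <- IRanges::setdiff(IRanges::IRanges(1L, record$length), occupied)

  part <- new_region_partition(record$id, record$length,
                               list(protein_coding = coding,
                                    structural_rna = structural,
                                    intron = intron,
                                    unclassified_orf = orf,
                                    intergenic = intergenic))
  stopifnot(sum(class_lengths(part)) == record$length)
  part
}

#' Codon-position site sets of all protein-coding genes
#'
#' Assigns each coding position its within-codon phase (1, 2 or 3) in
#' translation order across exon junctions, strand aware: minus-strand
#' genes are phased along the reverse complement.  Positions of CDSs whose
#' length is not divisible by 3 are included up to the last complete
#' codon, with a warning.  Unclassified (including intronic) ORFs never
#' contribute.
#'
#' @param record A [genome_record()].
#' @param include_stop Keep the terminal stop codon's sites (default
#'   drops them when the final codon is a stop).
#' @return List with integer vectors `pos1`, `pos2`, `pos3` of 0-based
#'   genome positions and `source_gene_count`.
#' @export
codon_position_sites <- function(record, include_stop = FALSE) {
  assert_scalar_flag(include_stop, "include_stop")
  feats <- Filter(function(f) f$kind == "protein_coding",
                  effective_features(record))
  if (!length(feats)) {
    stop(sprintf("record '%s' has no protein-coding features", record$id),
         call. = FALSE)
  }
  chars <- seq_chars(record$sequence)
  stops <- c("TAA", "TAG", "TGA")
  pos_sets <- list(pos1 = integer(0), pos2 = integer(0), pos3 = integer(0))
  for (feat in feats) {
    pos <- feature_positions(feat)
    n <- length(pos)
    if (n %% 3L != 0L) {
      warning(sprintf("CDS '%s' length %d not divisible by 3; truncating",
                      feat$gene_name, n), call. = FALSE)
      pos <- pos[seq_len((n %/% 3L) * 3L)]
      n <- length(pos)
    }
    if (n == 0L) next
    if (!include_stop && n >= 3L) {
      last <- chars[pos[(n - 2L):n] + 1L]
      if (feat$strand == "-") last <- comp_chars(last)
      if (paste(last, collapse = "") %in% stops) {
        pos <- pos[seq_len(n - 3L)]
        n <- n - 3L
      }
    }
    if (n == 0L) next
    phase <- rep.int(1:3, n %/% 3L)
    pos_sets$pos1 <- c(pos_sets$pos1, pos[phase == 1L])
    pos_sets$pos2 <- c(pos_sets$pos2, pos[phase == 2L])
    pos_sets$pos3 <- c(pos_sets$pos3, pos[phase == 3L])
  }
  c(pos_sets, list(source_gene_count = length(feats)))
}

#' Gene inventory of an annotated genome
#'
#' Counts protein-, rRNA- and tRNA-coding features; unclassified ORFs and
#' introns are never counted as genes.  By default every feature instance
#' counts (duplicate tRNA isoacceptors count once per copy); `dedupe`
#' collapses features sharing kind and gene name.
#'
#' @param record A [genome_record()].
#' @param dedupe Collapse duplicate (kind, gene name) pairs.
#' @return List with `n_protein`, `n_rrna`, `n_trna`, `n_total`, `names`.
#' @export
gene_inventory <- function(record, dedupe = FALSE) {
  assert_scalar_flag(dedupe, "dedupe")
  feats <- Filter(function(f) f$kind %in% c("protein_coding", "rRNA", "tRNA"),
                  effective_features(record))
  kinds <- vapply(feats, function(f) f$kind, character(1))
  names_ <- vapply(feats, function(f) f$gene_name, character(1))
  if (dedupe) {
    keep <- !duplicated(paste(kinds, names_, sep = "\r"))
    kinds <- kinds[keep]
    names_ <- names_[keep]
  }
  list(n_protein = sum(kinds == "protein_coding"),
       n_rrna = sum(kinds == "rRNA"),
       n_trna = sum(kinds == "tRNA"),
       n_total = length(kinds),
       names = names_)
}
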