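# Nucleotide-landscape statistics: GC content by region class and codon
# position, GC skew, noncoding fraction, amino-acid composition.

count_acgt <- function(chars) {
  c(A = sum(chars == "A"), C = sum(chars == "C"),
    G = sum(chars == "G"), T = sum(chars == "T"))
}

#' GC fraction of a nucleotide string
#'
#' `(G + C) / (A + C + G + T)`.  `N` and other ambiguity codes are
#' excluded from both numerator and denominator; an empty effective
#' denominator yields `NA` (undefined), never zero.
#'
#' @param seq Nucleotide string, or a character vector of single bases.
#' @return Fraction in `[0, 1]`, or `NA_real_`.
#' @examples
#' gc_fraction("GGCC")   # 1
#' gc_fraction("ATATN")  # 0 (the N is excluded)
#' @export
gc_fraction <- function(seq) {
  chars <- if (length(seq) == 1L && nchar(seq[1]) > 1L) seq_chars(seq) else seq
  n <- count_acgt(chars)
  denom <- sum(n)
  if (denom == 0L) return(NA_real_)
  unname((n["G"] + n["C"]) / denom)
}

#' GC skew of a nucleotide string
#'
#' `(G - C) / (G + C)` on the given strand; reverse complementing the
#' sequence flips the sign.  Zero G + C yields `NA`.
#'
#' @inheritParams gc_fraction
#' @return Value in `[-1, 1]`, or `NA_real_`.
#' @export
gc_skew <- function(seq) {
  chars <- if (length(seq) == 1L && nchar(seq[1]) > 1L) seq_chars(seq) else seq
  n <- count_acgt(chars)
  gc <- n["G"] + n["C"]
  if (gc == 0L) return(NA_real_)
  unname((n["G"] - n["C"]) / gc)
}

gc_of_ranges <- function(chars, ir) {
  if (sum(IRanges::width(ir)) == 0L) return(NA_real_)
  idx <- unlist(lapply(seq_along(ir), function(i) {
    seq.int(IRanges::start(ir)[i], IRanges::end(ir)[i])
  }), use.names = FALSE)
  gc_fraction(chars[idx])
}

#' GC content at first, second and third codon positions
#'
#' Evaluates [gc_fraction()] over the residues at each codon-position
#' site set, pooled over all contributing genes.  GC content is
#' strand-symmetric, so residues are read off the forward strand.
#'
#' @param record A [genome_record()].
#' @param sites A [codon_position_sites()] result for the same record
#'   (computed with defaults when omitted).
#' @return Named numeric vector `c(gc1, gc2, gc3)`.
#' @export
codon_position_gc <- function(record, sites = NULL) {
  if (is.null(sites)) sites <- codon_position_sites(record)
  chars <- seq_chars(record$sequence)
  c(gc1 = gc_fraction(chars[sites$pos1 + 1L]),
    gc2 = gc_fraction(chars[sites$pos2 + 1L]),
    gc3 = gc_fraction(chars[sites$pos3 + 1L]))
}

#' Full nucleotide-landscape report for one genome
#'
#' Computes the statistics a comparative organelle-genome table reports:
#' genome length, overall GC, GC1/GC2/GC3, GC of coding (protein +
#' structural-RNA pooled), intergenic and structural-RNA regions, GC
#' skew, and the noncoding percentage
#' `100 * (1 - (protein_coding + structural_rna) / length)` under which
#' introns and unclassified ORFs count as noncoding.  `repeat_pct` is
#' `NA` until filled from [find_maximal_repeats()] /
#' [repeat_coverage()].
#'
#' @param record A [genome_record()].
#' @param partition Optional precomputed [partition_genome()] result.
#' @param sites Optional precomputed [codon_position_sites()] result.
#' @param coding_protein_only Use only protein-coding positions (not
#'   structural RNA) for the "coding" GC column.
#' @return A one-row `data.frame` of class `landscape_report`.
#' @export
landscape_report <- function(record, partition = NULL, sites = NULL,
                             coding_protein_only = FALSE) {
  if (is.null(partition)) partition <- partition_genome(record)
  if (!identical(partition$genome_id, record$id) ||
      partition$length != record$length) {
    stop("partition does not belong to this record", call. = FALSE)
  }
  has_cds <- any(vapply(effective_features(record),
                        function(f) f$kind == "protein_coding", logical(1)))
  if (is.null(sites) && has_cds) sites <- codon_position_sites(record)
  chars <- seq_chars(record$sequence)
  cls <- partition$classes
  lens <- class_lengths(partition)

  coding_ir <- if (coding_protein_only) {
    cls$protein_coding
  } else {
    IRanges::union(cls$protein_coding, cls$structural_rna)
  }
  gc123 <- if (has_cds) codon_position_gc(record, sites) else
    c(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_)

  rep_df <- data.frame(
    genome_id = record$id,
    length_kb = record$length / 1000,
    gc_total_pct = 100 * gc_fraction(chars),
    gc1_pct = 100 * gc123[["gc1"]],
    gc2_pct = 100 * gc123[["gc2"]],
    gc3_pct = 100 * gc123[["gc3"]],
    gc_coding_pct = 100 * gc_of_ranges(chars, coding_ir),
    gc_intergenic_pct = 100 * gc_of_ranges(chars, cls$intergenic),
    gc_structural_rna_pct = 100 * gc_of_ranges(chars, cls$structural_rna),
    gc_skew = gc_skew(chars),
    noncoding_pct = 100 *
      (1 - (lens[["protein_coding"]] + lens[["structural_rna"]]) /
         record$length),
    n_genes = gene_inventory(record)$n_total,
    repeat_pct = NA_real_,
    stringsAsFactors = FALSE)
  class(rep_df) <- c("landscape_report", class(rep_df))
  rep_df
}

#' Amino-acid composition of all protein-coding genes
#'
#' Translates every complete codon of every protein-coding feature with
#' the standard genetic code and returns frequencies over the 20 amino
#' acids (stop codons excluded; frequencies sum to 1).  An internal stop
#' codon triggers a warning naming the gene and is skipped; codons with
#' ambiguity codes are skipped silently.
#'
#' @param record A [genome_record()] with at least one protein-coding
#'   feature.
#' @return Named numeric vector over the 20 amino acids (one-letter
#'   code, alphabetical).
#' @export
amino_acid_composition <- function(record) {
  feats <- Filter(function(f) f$kind == "protein_coding",
                  effective_features(record))
  if (!length(feats)) {
    stop(sprintf("record '%s' has no protein-coding features", record$id),
         call. = FALSE)
  }
  code <- Biostrings::GENETIC_CODE
  aa <- sort(setdiff(unique(code), "*"))
  counts <- stats::setNames(numeric(length(aa)), aa)
  for (feat in feats) {
    s <- feature_sequence(record, feat)
    nc <- nchar(s) %/% 3L
    if (nc == 0L) next
    codons <- substring(s, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
    trans <- unname(code[codons])
    internal_stop <- which(trans == "*" & seq_len(nc) < nc)
    if (length(internal_stop)) {
      warning(sprintf("internal stop codon in '%s' (codon %s); skipped",
                      feat$gene_name,
                      paste(internal_stop, collapse = ",")), call. = FALSE)
    }
    trans <- trans[!is.na(trans) & trans != "*"]
    if (length(trans)) {
      tab <- table(trans)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  if (sum(counts) == 0) return(counts)
  counts / sum(counts)
}
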