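# Phylogenomic supermatrix assembly: taxon-occupancy gene selection,
# concatenation with all-gap padding, and conserved-block column filtering
# with the four classic block-filter settings (no gaps, strict-majority
# conservation and flank counts, maximum non-conserved run, minimum block
# length).

#' Construct a gene alignment
#'
#' @param gene_name Gene identifier.
#' @param sequences Named character vector of equal-length aligned
#'   amino-acid sequences (gap character `-`), names are taxon labels.
#' @return Object of class `gene_alignment` with fields `gene_name`,
#'   `taxa`, `rows`, `width`.
#' @export
gene_alignment <- function(gene_name, sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named by taxon", call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) {
    stop(sprintf("gene '%s': duplicate sequences for taxon %s", gene_name,
                 names(sequences)[duplicated(names(sequences))][1]),
         call. = FALSE)
  }
  w <- unique(nchar(sequences))
  if (length(w) != 1L) {
    stop(sprintf("gene '%s': rows have unequal lengths", gene_name),
         call. = FALSE)
  }
  structure(list(gene_name = gene_name, taxa = names(sequences),
                 rows = toupper(unname(sequences)), width = w),
            class = "gene_alignment")
}

#' Read one gene alignment from an aligned FASTA file
#'
#' @param path FASTA path; the gene name defaults to the file stem.
#' @param gene_name Override for the gene name.
#' @return A [gene_alignment()].
#' @export
read_gene_alignment <- function(path, gene_name = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  gene_name <- gene_name %||% sub("\\.[^.]*$", "", basename(path))
  seqs <- stats::setNames(as.character(ss),
                          vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L))
  gene_alignment(gene_name, seqs)
}

#' Select genes by taxon occupancy
#'
#' A gene is selected iff the fraction of reference taxa for which it has
#' a sequence is at least `threshold` (default 0.7: presence in at least
#' 70% of the species to be included in the final concatenation).
#'
#' @param alignments List of [gene_alignment()]s.
#' @param taxa Reference taxon list.
#' @param threshold Occupancy threshold in `(0, 1]`.
#' @return Character vector of selected gene names.
#' @export
select_genes <- function(alignments, taxa, threshold = 0.7) {
  if (!length(taxa)) stop("empty reference taxon list", call. = FALSE)
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  keep <- vapply(alignments, function(al) {
    sum(taxa %in% al$taxa) / length(taxa) >= threshold
  }, logical(1))
  vapply(alignments[keep], function(al) al$gene_name, character(1))
}

#' Concatenate gene alignments into a supermatrix
#'
#' Each taxon's row is the in-order join of its per-gene sequences, with
#' an all-gap block where the taxon is missing the gene.
#'
#' @param alignments List of [gene_alignment()]s (the selected genes, in
#'   order).
#' @param taxa Reference taxon list defining the rows.
#' @return Object of class `supermatrix`: `taxa`, `rows` (character
#'   vector), `width`, `gene_boundaries` (`data.frame` of 1-based
#'   inclusive column spans per gene), `occupancy` (per-taxon non-gap
#'   fraction).
#' @export
concatenate_alignments <- function(alignments, taxa) {
  if (!length(alignments)) stop("no gene alignments given", call. = FALSE)
  if (!length(taxa)) stop("empty reference taxon list", call. = FALSE)
  widths <- vapply(alignments, function(al) al$width, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- vapply(taxa, function(tx) {
    paste(vapply(alignments, function(al) {
      k <- match(tx, al$taxa)
      if (is.na(k)) strrep("-", al$width) else al$rows[k]
    }, character(1)), collapse = "")
  }, character(1))
  width <- sum(widths)
  occupancy <- vapply(rows, function(r) {
    1 - lengths(regmatches(r, gregexpr("-", r, fixed = TRUE))) / width
  }, numeric(1))
  structure(list(
    taxa = taxa, rows = unname(rows), width = width,
    gene_boundaries = data.frame(
      gene = vapply(alignments, function(al) al$gene_name, character(1)),
      start = starts, end = ends, stringsAsFactors = FALSE),
    occupancy = unname(occupancy)),
    class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d genes\n",
              length(x$taxa), x$width, nrow(x$gene_boundaries)))
  invisible(x)
}

#' Filter supermatrix columns into conserved blocks
#'
#' A column is *gapped* when any row has `-`; *conserved* when its most
#' frequent residue count (gaps never counted) is at least
#' `min_conserved`.  Retained columns form blocks in which (i) no gapped
#' column appears when `allow_gaps = FALSE`, (ii) no run of more than
#' `max_noncon` consecutive non-conserved columns survives, (iii) blocks
#' are trimmed until flanked on both ends by columns whose top residue
#' count reaches `min_flank`, and (iv) blocks shorter than `min_block`
#' are dropped.  Column order is preserved and gene boundaries are
#' remapped.  Defaults for `min_conserved`/`min_flank` are
#' `floor(T/2) + 1` (50% of the number of taxa plus one, under the
#' strict-majority reading).
#'
#' @param matrix A [concatenate_alignments()] result.
#' @param min_conserved,min_flank Minimum residue counts for conserved
#'   and flank positions.
#' @param max_noncon Maximum run of contiguous non-conserved positions
#'   (default 10).
#' @param min_block Minimum block length (default 8).
#' @param allow_gaps Keep gapped columns eligible (default `FALSE`: no
#'   gaps allowed).
#' @return A filtered `supermatrix`; `$kept_columns` records the
#'   original column indices.
#' @export
filter_columns <- function(matrix, min_conserved = NULL, min_flank = NULL,
                           max_noncon = 10L, min_block = 8L,
                           allow_gaps = FALSE) {
  stopifnot(inherits(matrix, "supermatrix"))
  T_ <- length(matrix$taxa)
  min_conserved <- min_conserved %||% (T_ %/% 2L + 1L)
  min_flank <- min_flank %||% (T_ %/% 2L + 1L)
  if (min_conserved > T_ || min_flank > T_) {
    stop("min_conserved/min_flank cannot exceed the taxon count",
         call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(matrix$rows, "", fixed = TRUE))
  W <- ncol(chars)
  top_count <- integer(W)
  gapped <- logical(W)
  for (c_ in seq_len(W)) {
    col <- chars[, c_]
    gapped[c_] <- any(col == "-")
    res <- col[col != "-"]
    top_count[c_] <- if (length(res)) max(tabulate(factor(res))) else 0L
  }
  conserved <- top_count >= min_conserved
  eligible <- if (allow_gaps) rep(TRUE, W) else !gapped

  keep <- logical(W)
  # Segments of eligible columns, scanned left to right.
  r <- rle(eligible)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  for (s_ in which(r$values)) {
    cols <- seq.int(seg_start[s_], seg_end[s_])
    # Break at runs of > max_noncon consecutive non-conserved columns.
    rc <- rle(conserved[cols])
    ce <- cumsum(rc$lengths)
    cs <- ce - rc$lengths + 1L
    good <- rep(TRUE, length(cols))
    for (q in which(!rc$values & rc$lengths > max_noncon)) {
      good[cs[q]:ce[q]] <- FALSE
    }
    rg <- rle(good)
    ge <- cumsum(rg$lengths)
    gs <- ge - rg$lengths + 1L
    for (q in which(rg$values)) {
      blk <- cols[gs[q]:ge[q]]
      # Trim to flank-qualified ends.
      while (length(blk) && top_count[blk[1]] < min_flank) blk <- blk[-1]
      while (length(blk) && top_count[blk[length(blk)]] < min_flank) {
        blk <- blk[-length(blk)]
      }
      if (length(blk) >= min_block) keep[blk] <- TRUE
    }
  }
  kept <- which(keep)
  new_rows <- vapply(seq_len(nrow(chars)), function(i) {
    paste(chars[i, kept], collapse = "")
  }, character(1))
  gb <- matrix$gene_boundaries
  n_kept <- vapply(seq_len(nrow(gb)), function(g) {
    sum(kept >= gb$start[g] & kept <= gb$end[g])
  }, integer(1))
  new_end <- cumsum(n_kept)
  new_start <- ifelse(n_kept > 0L, new_end - n_kept + 1L, NA_integer_)
  out <- structure(list(
    taxa = matrix$taxa, rows = new_rows, width = length(kept),
    gene_boundaries = data.frame(gene = gb$gene, start = new_start,
                                 end = ifelse(n_kept > 0L, new_end,
                                              NA_integer_),
                                 stringsAsFactors = FALSE),
    occupancy = vapply(new_rows, function(rw) {
      if (!nchar(rw)) return(NA_real_)
      1 - lengths(regmatches(rw, gregexpr("-", rw, fixed = TRUE))) / nchar(rw)
    }, numeric(1), USE.NAMES = FALSE),
    kept_columns = kept),
    class = "supermatrix")
  out
}

#' Write a supermatrix in relaxed PHYLIP format
#'
#' @param matrix A `supermatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(matrix$taxa), matrix$width), con)
  writeLines(sprintf("%s  %s", matrix$taxa, matrix$rows), con)
  invisible(path)
}

#' Per-taxon occupancy report of a supermatrix
#'
#' @param matrix A `supermatrix`.
#' @param path Optional TSV output path.
#' @return `data.frame` with `taxon` and `occupancy`.
#' @export
occupancy_report <- function(matrix, path = NULL) {
  df <- data.frame(taxon = matrix$taxa,
                   occupancy = round(matrix$occupancy, 6),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
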