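#' Annotated genome records
#'
#' A `genome_record` is the unit every genomic computation in the package
#' consumes: one sequence (linear or circular-mapping) plus an ordered list
#' of annotated features.  All internal coordinates are 0-based half-open;
#' conversion to and from the 1-based inclusive convention of GenBank
#' happens only at I/O boundaries.
#'
#' @param id Accession or identifier string.
#' @param sequence Nucleotide string over the IUPAC alphabet (case
#'   insensitive on input; stored uppercase).
#' @param circular Logical topology flag.
#' @param features List of features built with [feature()].
#' @return An object of class `genome_record` with fields `id`, `length`,
#'   `circular`, `sequence` and `features`.
#' @seealso [feature()], [read_genome_record()]
#' @export
genome_record <- function(id, sequence, circular = FALSE, features = list()) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  assert_scalar_flag(circular, "circular")
  sequence <- toupper(sequence)
  chars <- seq_chars(sequence)
  bad <- setdiff(unique(chars), IUPAC_CHARS)
  if (length(bad)) {
    stop(sprintf("record '%s': residues outside the IUPAC alphabet: %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  rec <- structure(
    list(id = id, length = nchar(sequence), circular = circular,
         sequence = sequence, features = features),
    class = "genome_record")
  validate_genome_record(rec)
  rec
}

#' Construct an annotated feature
#'
#' Exons are stored in join order: the order in which segments are spliced
#' on the forward strand.  For a minus-strand feature the translated
#' sequence is the reverse complement of the join-order concatenation,
#' matching GenBank `complement(join(...))` semantics.  A feature crossing
#' the origin of a circular record is represented by two (or more) exons in
#' join order.
#'
#' @param kind One of `"protein_coding"`, `"rRNA"`, `"tRNA"`, `"intron"`,
#'   `"unclassified_orf"`, `"other"`.
#' @param exons Two-column matrix of 0-based half-open `[start, end)`
#'   intervals, one row per exon, in join order.
#' @param strand `"+"` or `"-"`.
#' @param gene_name Gene symbol, or `""` when unknown.
#' @param qualifiers Named list of raw qualifier strings.
#' @return An object of class `genome_feature`.
#' @export
feature <- function(kind, exons, strand = "+", gene_name = "",
                    qualifiers = list()) {
  kinds <- c("protein_coding", "rRNA", "tRNA", "intron",
             "unclassified_orf", "other")
  if (!kind %in% kinds) {
    stop("unknown feature kind: ", kind, call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("feature needs at least one exon", call. = FALSE)
  if (any(exons[, 1] >= exons[, 2])) {
    stop("every exon must satisfy start < end (wrap exons are split on ingest)",
         call. = FALSE)
  }
  structure(list(kind = kind, gene_name = gene_name, strand = strand,
                 exons = exons, qualifiers = qualifiers),
            class = "genome_feature")
}

feature_length <- function(feat) sum(feat$exons[, 2] - feat$exons[, 1])

validate_genome_record <- function(rec) {
  if (rec$length != nchar(rec$sequence)) {
    stop("record length does not match sequence length", call. = FALSE)
  }
  for (feat in rec$features) {
    if (!inherits(feat, "genome_feature")) {
      stop("features must be built with feature()", call. = FALSE)
    }
    if (any(feat$exons[, 1] < 0L) || any(feat$exons[, 2] > rec$length)) {
      stop(sprintf(
        "record '%s': feature '%s' extends beyond [0, %d) after normalization",
        rec$id, feat$gene_name, rec$length), call. = FALSE)
    }
    if (feat$kind == "protein_coding" && feature_length(feat) %% 3L != 0L) {
      warning(sprintf(
        "record '%s': CDS '%s' length %d not divisible by 3",
        rec$id, feat$gene_name, feature_length(feat)), call. = FALSE)
    }
  }
  invisible(rec)
}

#' @export
print.genome_record <- function(x, ...) {
  kinds <- vapply(x$features, function(f) f$kind, character(1))
  cat(sprintf("<genome_record> %s: %d nt, %s, %d features\n", x$id, x$length,
              if (x$circular) "circular" else "linear", length(x$features)))
  if (length(kinds)) print(table(kinds))
  invisible(x)
}

# Genomic positions (0-based) of a feature in translation order: join order
# on the plus strand, reversed for the minus strand.
feature_positions <- function(feat) {
  pos <- unlist(lapply(seq_len(nrow(feat$exons)), function(i) {
    seq.int(feat$exons[i, 1], feat$exons[i, 2] - 1L)
  }), use.names = FALSE)
  if (feat$strand == "-") rev(pos) else pos
}

#' Extract the spliced, strand-corrected sequence of a feature
#'
#' Joins the exon pieces (rejoining circular-wrap splits) and reverse
#' complements for minus-strand features, yielding the sequence in
#' translation orientation.
#'
#' @param record A [genome_record()].
#' @param feat A [feature()] of that record.
#' @return Character scalar.
#' @export
feature_sequence <- function(record, feat) {
  pieces <- vapply(seq_len(nrow(feat$exons)), function(i) {
    substr(record$sequence, feat$exons[i, 1] + 1L, feat$exons[i, 2])
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (feat$strand == "-") revcomp(s) else s
}

#' Rotate a circular genome record
#'
#' Shifts the sequence origin by `offset` positions; features are remapped
#' modulo the genome length and any feature interval that comes to cross
#' the new origin is split into wrap exons.  Region-class statistics are
#' invariant under rotation.
#'
#' @param record A circular [genome_record()].
#' @param offset Integer shift (the base at position `offset` becomes
#'   position 0).
#' @return The rotated `genome_record`.
#' @export
rotate_record <- function(record, offset) {
  if (!record$circular) stop("rotate_record() requires a circular record",
                             call. = FALSE)
  L <- record$length
  offset <- ((as.integer(offset) %% L) + L) %% L
  if (offset == 0L) return(record)
  s <- paste0(substr(record$sequence, offset + 1L, L),
              substr(record$sequence, 1L, offset))
  feats <- lapply(record$features, function(f) {
    new_exons <- list()
    for (i in seq_len(nrow(f$exons))) {
      a <- (f$exons[i, 1] - offset) %% L
      len <- f$exons[i, 2] - f$exons[i, 1]
      if (a + len <= L) {
        new_exons[[length(new_exons) + 1L]] <- c(a, a + len)
      } else {
        new_exons[[length(new_exons) + 1L]] <- c(a, L)
        new_exons[[length(new_exons) + 1L]] <- c(0L, a + len - L)
      }
    }
    f$exons <- matrix(as.integer(unlist(new_exons)), ncol = 2L, byrow = TRUE,
                      dimnames = list(NULL, c("start", "end")))
    f
  })
  genome_record(record$id, s, circular = TRUE, features = feats)
}
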