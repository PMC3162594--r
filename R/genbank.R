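# GenBank flat-file reader and a minimal writer.
#
# Only the pieces of the format the pipeline touches are implemented:
# LOCUS (length + topology), the feature table (locations with
# complement/join and circular wrap, plus qualifiers) and ORIGIN.  All
# 1-based inclusive source coordinates are converted to 0-based half-open
# on ingest; the conversion back happens only in write_genbank().

GENBANK_KIND_MAP <- c(CDS = "protein_coding", rRNA = "rRNA", tRNA = "tRNA",
                      intron = "intron")

parse_genbank <- function(lines, source = "<text>") {
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) {
    stop(sprintf("%s: no LOCUS line; not a GenBank flat file", source),
         call. = FALSE)
  }
  locus <- lines[locus_i[1]]
  m <- regmatches(locus, regexec("^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp", locus))[[1]]
  if (length(m) < 3L) {
    stop(sprintf("%s line %d: malformed LOCUS line", source, locus_i[1]),
         call. = FALSE)
  }
  id <- m[2]
  decl_len <- as.integer(m[3])
  circular <- grepl("\\bcircular\\b", locus, ignore.case = TRUE)

  # Sequence: ORIGIN .. "//"
  ori_i <- grep("^ORIGIN", lines)
  if (!length(ori_i)) {
    stop(sprintf("%s: no ORIGIN section in record '%s'", source, id),
         call. = FALSE)
  }
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > ori_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[seq.int(ori_i[1] + 1L, end_i - 1L)]
  sequence <- toupper(gsub("[0-9 \t]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) != decl_len) {
    warning(sprintf("%s: record '%s' declares %d bp but ORIGIN has %d",
                    source, id, decl_len, nchar(sequence)), call. = FALSE)
  }

  # Feature table: FEATURES .. ORIGIN
  feat_i <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_i) && feat_i[1] < ori_i[1]) {
    block <- lines[seq.int(feat_i[1] + 1L, ori_i[1] - 1L)]
    block_line0 <- feat_i[1]
    entries <- parse_feature_block(block, block_line0, source)
    features <- lapply(entries, function(e) {
      build_feature(e, L = nchar(sequence), circular = circular,
                    source = source)
    })
    features <- features[!vapply(features, is.null, logical(1))]
  }
  genome_record(id, sequence, circular = circular, features = features)
}

# Split the raw feature table into (key, location, qualifiers, line) entries.
parse_feature_block <- function(block, line0, source) {
  entries <- list()
  cur <- NULL
  mode <- "location"
  for (k in seq_along(block)) {
    line <- block[k]
    if (grepl("^ {5}\\S", line)) {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      parts <- regmatches(line, regexec("^ {5}(\\S+)\\s+(\\S.*)$", line))[[1]]
      if (length(parts) < 3L) {
        stop(sprintf("%s line %d: malformed feature line: '%s'",
                     source, line0 + k, line), call. = FALSE)
      }
      cur <- list(key = parts[2], location = parts[3],
                  qualifiers = character(0), line = line0 + k)
      mode <- "location"
    } else if (grepl("^\\s{10,}\\S", line) && !is.null(cur)) {
      txt <- sub("^\\s+", "", line)
      if (startsWith(txt, "/")) {
        cur$qualifiers <- c(cur$qualifiers, txt)
        mode <- "qualifier"
      } else if (mode == "location") {
        cur$location <- paste0(cur$location, txt)
      } else {
        n <- length(cur$qualifiers)
        sep <- if (grepl("^/translation=", cur$qualifiers[n])) "" else " "
        cur$qualifiers[n] <- paste0(cur$qualifiers[n], sep, txt)
      }
    } else if (nzchar(trimws(line))) {
      stop(sprintf("%s line %d: unparseable feature-table line: '%s'",
                   source, line0 + k, line), call. = FALSE)
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
  entries
}

parse_qualifiers <- function(quals) {
  out <- list()
  for (q in quals) {
    m <- regmatches(q, regexec("^/([A-Za-z_0-9]+)(?:=(.*))?$", q))[[1]]
    if (length(m) < 2L) next
    key <- m[2]
    val <- if (length(m) >= 3L && nzchar(m[3])) m[3] else "true"
    val <- gsub('^"|"$', "", val)
    if (is.null(out[[key]])) out[[key]] <- val
  }
  out
}

# Parse a GenBank location string into strand + join-order exon matrix.
parse_location <- function(loc, L, circular, source = "<text>", line = NA) {
  loc0 <- loc
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  segs <- loc
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    segs <- strsplit(inner, ",", fixed = TRUE)[[1]]
  }
  seg_comp <- grepl("^complement\\(", segs)
  if (any(seg_comp)) {
    if (!all(seg_comp) || strand == "-") {
      stop(sprintf("%s line %s: mixed-strand location not supported: '%s'",
                   source, line, loc0), call. = FALSE)
    }
    strand <- "-"
    segs <- sub("^complement\\((.*)\\)$", "\\1", segs)
    # join(complement(b), complement(a)) reads segments in translation
    # order; our storage is forward join order, i.e. the reverse.
    segs <- rev(segs)
  }
  exons <- list()
  for (seg in segs) {
    m <- regmatches(seg, regexec("^<?(\\d+)(?:\\.\\.>?(\\d+))?$", seg))[[1]]
    if (length(m) < 2L) {
      stop(sprintf("%s line %s: cannot parse location segment '%s' in '%s'",
                   source, line, seg, loc0), call. = FALSE)
    }
    a <- as.integer(m[2])
    b <- if (length(m) >= 3L && nzchar(m[3])) as.integer(m[3]) else a
    if (a <= b) {
      exons[[length(exons) + 1L]] <- c(a - 1L, b)
    } else if (circular) {
      # Origin-spanning segment on a circular record: split into two exons.
      exons[[length(exons) + 1L]] <- c(a - 1L, L)
      exons[[length(exons) + 1L]] <- c(0L, b)
    } else {
      stop(sprintf(
        "%s line %s: start > end in '%s' but record is not circular",
        source, line, seg), call. = FALSE)
    }
  }
  list(strand = strand,
       exons = matrix(as.integer(unlist(exons)), ncol = 2L, byrow = TRUE))
}

build_feature <- function(entry, L, circular, source) {
  key <- entry$key
  if (key %in% c("source", "gene", "misc_feature", "repeat_region",
                 "D-loop", "exon")) {
    return(NULL)  # not part of the region-class model
  }
  kind <- GENBANK_KIND_MAP[key]
  if (is.na(kind)) return(NULL)
  loc <- parse_location(entry$location, L, circular, source, entry$line)
  quals <- parse_qualifiers(entry$qualifiers)
  gname <- quals$gene %||% ""
  prod <- quals$product %||% ""
  if (kind == "protein_coding") {
    unnamed <- !nzchar(gname)
    orf_like <- grepl("^orf", gname, ignore.case = TRUE) ||
      (unnamed && (!nzchar(prod) ||
                   grepl("^orf|hypothetical", prod, ignore.case = TRUE)))
    if (orf_like) kind <- "unclassified_orf"
  }
  if (!nzchar(gname) && nzchar(prod)) gname <- prod
  feature(kind, loc$exons, strand = loc$strand, gene_name = gname,
          qualifiers = quals)
}

#' Write a genome record as a GenBank flat file
#'
#' Emits LOCUS, a feature table (CDS/rRNA/tRNA/intron with
#' `join`/`complement` locations, wrap exons rejoined as an
#' origin-spanning segment) and ORIGIN.  `read_genome_record()` on the
#' output reconstructs the record.
#'
#' @param record A [genome_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (record$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s SYN 01-JAN-2026",
                     record$id, record$length, topo), con)
  writeLines(sprintf("DEFINITION  synthetic organelle genome %s.", record$id),
             con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", record$length), con)
  rev_map <- c(protein_coding = "CDS", rRNA = "rRNA", tRNA = "tRNA",
               intron = "intron", unclassified_orf = "CDS",
               other = "misc_feature")
  for (feat in record$features) {
    segs <- apply(feat$exons, 1L, function(e) sprintf("%d..%d", e[1] + 1L, e[2]))
    # Rejoin a circular-wrap split ([a, L) + [0, b)) into one a..b segment.
    if (record$circular && nrow(feat$exons) >= 2L) {
      i <- 1L
      merged <- character(0)
      while (i <= nrow(feat$exons)) {
        if (i < nrow(feat$exons) &&
            feat$exons[i, 2] == record$length && feat$exons[i + 1L, 1] == 0L) {
          merged <- c(merged, sprintf("%d..%d", feat$exons[i, 1] + 1L,
                                      feat$exons[i + 1L, 2]))
          i <- i + 2L
        } else {
          merged <- c(merged, segs[i])
          i <- i + 1L
        }
      }
      segs <- merged
    }
    loc <- if (length(segs) > 1L) {
      sprintf("join(%s)", paste(segs, collapse = ","))
    } else {
      segs
    }
    if (feat$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", rev_map[[feat$kind]], loc), con)
    quals <- feat$qualifiers
    if (feat$kind == "unclassified_orf" && is.null(quals$product)) {
      quals$product <- sprintf("hypothetical protein %s", feat$gene_name)
    } else if (nzchar(feat$gene_name) && is.null(quals$gene) &&
               feat$kind != "unclassified_orf") {
      quals$gene <- feat$gene_name
    }
    for (key in names(quals)) {
      val <- quals[[key]]
      if (identical(val, "true")) {
        writeLines(sprintf("                     /%s", key), con)
      } else {
        writeLines(sprintf("                     /%s=\"%s\"", key, val), con)
      }
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  starts <- seq.int(1L, record$length, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, record$length))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
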