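# Maximal exact repeat discovery: direct and inverted (palindromic)
# repeats within a genome, and exact segments shared between two genomes.
#
# Algorithm: k-mer seed (k = min_len) and maximal extension.  Seeds are
# "left-locked" -- a seed pair is kept only when the characters just left
# of both copies differ -- so each maximal pair is seeded exactly once, at
# its leftmost k-mer, and recovered in full by rightward extension.  Any
# matched region is necessarily pure A/C/G/T because ambiguity codes are
# encoded as per-position unique sentinels that never compare equal.

comp_code <- function(code, shift) {
  out <- ifelse(code <= 4L, 5L - code, code + shift)
  as.integer(out)
}

# Starts (1-based) of k-windows free of ambiguity codes.
valid_kmer_starts <- function(code, k) {
  n <- length(code)
  if (n < k) return(integer(0))
  bad <- cumsum(c(0L, as.integer(code > 4L)))
  i <- seq_len(n - k + 1L)
  i[bad[i + k] - bad[i] == 0L]
}

extend_right <- function(xa, xb, i, j, k) {
  len <- k
  na_ <- length(xa)
  nb_ <- length(xb)
  repeat {
    pa <- i + len
    pb <- j + len
    m <- min(na_ - pa + 1L, nb_ - pb + 1L, 256L)
    if (m <= 0L) break
    d <- which(xa[pa:(pa + m - 1L)] != xb[pb:(pb + m - 1L)])
    if (length(d)) {
      len <- len + d[1] - 1L
      break
    }
    len <- len + m
    if (m < 256L) break
  }
  len
}

# All maximal matched pairs (i, j, len >= k) between integer-coded xa and
# xb.  self = TRUE restricts to i < j on a single sequence.
seed_extend_pairs <- function(xa, xb, sa, sb, k, self = FALSE) {
  ia <- valid_kmer_starts(xa, k)
  if (!length(ia)) return(data.frame(i = integer(0), j = integer(0),
                                     len = integer(0)))
  ka <- substring(sa, ia, ia + k - 1L)
  if (self) {
    grp <- split(ia, ka)
    grp <- grp[lengths(grp) >= 2L]
    if (!length(grp)) return(data.frame(i = integer(0), j = integer(0),
                                        len = integer(0)))
    prs <- do.call(cbind, lapply(grp, function(g) utils::combn(sort(g), 2L)))
    i <- prs[1, ]
    j <- prs[2, ]
  } else {
    jb <- valid_kmer_starts(xb, k)
    if (!length(jb)) return(data.frame(i = integer(0), j = integer(0),
                                       len = integer(0)))
    kb <- substring(sb, jb, jb + k - 1L)
    grp <- split(ia, ka)
    hits <- grp[kb]
    lens <- lengths(hits)
    if (!sum(lens)) return(data.frame(i = integer(0), j = integer(0),
                                      len = integer(0)))
    j <- rep.int(jb, lens)
    i <- unlist(hits, use.names = FALSE)
  }
  # Left-lock: keep only diagonal-leftmost seeds (distinct sentinels make
  # sequence boundaries always left-maximal).
  la <- c(-1L, xa)
  lb <- c(-2L, xb)
  keep <- la[i] != lb[j]
  i <- i[keep]
  j <- j[keep]
  if (!length(i)) return(data.frame(i = integer(0), j = integer(0),
                                    len = integer(0)))
  len <- mapply(extend_right, i = i, j = j,
                MoreArgs = list(xa = xa, xb = xb, k = k))
  data.frame(i = i, j = j, len = as.integer(len))
}

low_complexity <- function(s) {
  n <- nchar(s)
  if (n <= 50L) return(FALSE)
  ch <- seq_chars(s)
  all(ch[-(1:2)] == ch[seq_len(n - 2L)])  # period <= 2
}

wrap_extend <- function(chars, circular, min_len, wrap = 300L) {
  n <- length(chars)
  if (!circular || n <= min_len) return(chars)
  c(chars, chars[seq_len(min(n - 1L, wrap + min_len))])
}

#' Find maximal exact repeats within a genome
#'
#' Reports every maximal repeated pair of length at least `min_len`:
#' the two copies are identical (`forward`) or exact reverse complements
#' (`inverted`), and extending both copies one position left or right
#' breaks the match.  Circular topology is honoured by analysing the
#' sequence plus a wrap extension (default 300 nt beyond `min_len`) and
#' deduplicating hits mapped back modulo the genome length.  Tandem
#' (self-overlapping) copies are reported once per maximal pair; pairs
#' lying in a low-complexity run (period at most 2, longer than 50 nt)
#' are flagged, not removed.
#'
#' @param record A [genome_record()], or a plain nucleotide string.
#' @param min_len Minimum repeat length; must be >= 8 (guards quadratic
#'   blowup on trivial matches).  Default 20, the shortest repeat length
#'   of interest in GC-rich organelle genomes.
#' @param orientations Subset of `c("forward", "inverted")`.
#' @param wrap Circular wrap-extension length.
#' @return `data.frame` with columns `orientation`, `pos_a`, `pos_b`
#'   (0-based starts, `pos_a < pos_b` for forward hits and canonical
#'   ordering for inverted ones), `length`, `gc_pct`, `low_complexity`.
#' @export
find_maximal_repeats <- function(record, min_len = 20L,
                                 orientations = c("forward", "inverted"),
                                 wrap = 300L) {
  if (min_len < 8L) stop("min_len must be >= 8", call. = FALSE)
  orientations <- match.arg(orientations, several.ok = TRUE)
  if (inherits(record, "genome_record")) {
    s <- record$sequence
    circular <- record$circular
  } else {
    s <- toupper(as.character(record))
    circular <- FALSE
  }
  n <- nchar(s)
  if (n < min_len) stop("sequence shorter than min_len", call. = FALSE)
  chars <- seq_chars(s)
  ext <- wrap_extend(chars, circular, min_len, wrap)
  m <- length(ext)
  sx <- paste(ext, collapse = "")
  x <- encode_seq(ext)

  out <- list()
  seen <- new.env(parent = emptyenv())
  add_hit <- function(orientation, a, b, len, rep_seq) {
    if (len > n) return(invisible())
    key <- paste(orientation, a, b, sep = ":")
    prev <- get0(key, envir = seen)
    if (!is.null(prev) && prev >= len) return(invisible())
    assign(key, len, envir = seen)
    out[[key]] <<- data.frame(orientation = orientation, pos_a = a, pos_b = b,
                              length = len, gc_pct = 100 * gc_fraction(rep_seq),
                              low_complexity = low_complexity(rep_seq),
                              stringsAsFactors = FALSE)
    invisible()
  }

  if ("forward" %in% orientations) {
    prs <- seed_extend_pairs(x, x, sx, sx, min_len, self = TRUE)
    for (r in seq_len(nrow(prs))) {
      a <- (prs$i[r] - 1L) %% n
      b <- (prs$j[r] - 1L) %% n
      if (a == b) next
      if (a > b) { tmp <- a; a <- b; b <- tmp }
      add_hit("forward", a, b, prs$len[r],
              substr(sx, prs$i[r], prs$i[r] + prs$len[r] - 1L))
    }
  }
  if ("inverted" %in% orientations) {
    ychars <- rev(comp_chars(ext))
    sy <- paste(ychars, collapse = "")
    y <- comp_code(rev(x), shift = m)
    prs <- seed_extend_pairs(x, y, sx, sy, min_len, self = FALSE)
    for (r in seq_len(nrow(prs))) {
      p <- m - prs$j[r] - prs$len[r] + 2L  # partner start in forward coords
      a <- (prs$i[r] - 1L) %% n
      b <- (p - 1L) %% n
      if (a == b) next
      if (a > b) { tmp <- a; a <- b; b <- tmp }
      add_hit("inverted", a, b, prs$len[r],
              substr(sx, prs$i[r], prs$i[r] + prs$len[r] - 1L))
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else {
    data.frame(orientation = character(0), pos_a = integer(0),
               pos_b = integer(0), length = integer(0), gc_pct = numeric(0),
               low_complexity = logical(0))
  }
  rownames(hits) <- NULL
  if (circular) {
    hits <- drop_contained_pairs(hits, "pos_a", "pos_b", n, n,
                                 allow_swap = TRUE)
  }
  hits[order(-hits$length, hits$pos_a, hits$pos_b), , drop = FALSE]
}

# Drop circular-boundary artefacts: a pair aligned inside a longer pair
# (modulo the genome length) is extendable across the origin, hence not
# maximal.  allow_swap covers the two copy-role assignments of a
# within-genome pair.
drop_contained_pairs <- function(df, acol, bcol, na, nb, allow_swap) {
  if (nrow(df) < 2L) return(df)
  keep <- rep(TRUE, nrow(df))
  ord <- order(df$length)
  for (ri in seq_along(ord)) {
    r <- ord[ri]
    for (si in seq.int(ri + 1L, length(ord))) {
      if (si > length(ord)) break
      s_ <- ord[si]
      if (df$length[s_] <= df$length[r]) next
      if (df$orientation[r] != df$orientation[s_]) next
      lr <- df$length[r]
      ls <- df$length[s_]
      fits <- function(a1, b1) {
        da <- (df[[acol]][r] - a1) %% na
        db <- (df[[bcol]][r] - b1) %% nb
        if (da + lr > ls) return(FALSE)
        if (df$orientation[r] == "forward") db == da else db == ls - lr - da
      }
      hit <- fits(df[[acol]][s_], df[[bcol]][s_]) ||
        (allow_swap && fits(df[[bcol]][s_], df[[acol]][s_]))
      if (hit) {
        keep[r] <- FALSE
        break
      }
    }
  }
  df[keep, , drop = FALSE]
}

# 0-based [start, start+len) intervals -> IRanges, splitting circular wrap.
hit_ranges <- function(starts, lens, genome_len) {
  pieces <- list()
  for (r in seq_along(starts)) {
    a <- starts[r]
    e <- a + lens[r]
    if (e <= genome_len) {
      pieces[[length(pieces) + 1L]] <- c(a, e)
    } else {
      pieces[[length(pieces) + 1L]] <- c(a, genome_len)
      pieces[[length(pieces) + 1L]] <- c(0L, e - genome_len)
    }
  }
  if (!length(pieces)) return(IRanges::IRanges())
  mat <- do.call(rbind, pieces)
  ir_from0(mat[, 1], mat[, 2])
}

#' Fraction of a genome covered by repeat copies
#'
#' Union length of all repeat-copy intervals divided by genome length;
#' overlapping copies are counted once.
#'
#' @param hits A [find_maximal_repeats()] result.
#' @param length Genome length in nt.
#' @return Fraction in `[0, 1]`.
#' @export
repeat_coverage <- function(hits, length) {
  if (nrow(hits) == 0L) return(0)
  ir <- hit_ranges(c(hits$pos_a, hits$pos_b), rep(hits$length, 2L), length)
  sum(IRanges::width(IRanges::reduce(ir))) / length
}

#' Exact segments shared between two genomes
#'
#' All maximal cross-genome exact matches of length at least `min_len`,
#' in both orientations, plus a summary: the number of distinct merged
#' repeat sites in each genome and the total shared length (union in
#' genome A).
#'
#' @param record_a,record_b Two [genome_record()]s (or plain strings).
#' @param min_len Minimum segment length (>= 8); default 30, which makes
#'   chance matches between genomes of a few hundred kb vanishingly
#'   unlikely.
#' @param orientations Subset of `c("forward", "inverted")`.
#' @return List with `segments` (`data.frame`: `orientation`, `pos_in_a`,
#'   `pos_in_b`, `length`), `n_sites_a`, `n_sites_b`, `total_shared_nt`.
#' @export
shared_repeats <- function(record_a, record_b, min_len = 30L,
                           orientations = c("forward", "inverted")) {
  if (min_len < 8L) stop("min_len must be >= 8", call. = FALSE)
  orientations <- match.arg(orientations, several.ok = TRUE)
  get_seq <- function(r) {
    if (inherits(r, "genome_record")) {
      list(s = r$sequence, circ = r$circular, id = r$id)
    } else {
      list(s = toupper(as.character(r)), circ = FALSE, id = "seq")
    }
  }
  A <- get_seq(record_a)
  B <- get_seq(record_b)
  if (identical(A$s, B$s)) {
    stop("shared_repeats() needs two distinct records; ",
         "use find_maximal_repeats() within one genome", call. = FALSE)
  }
  na <- nchar(A$s)
  nb <- nchar(B$s)
  ach <- wrap_extend(seq_chars(A$s), A$circ, min_len)
  bch <- wrap_extend(seq_chars(B$s), B$circ, min_len)
  sa <- paste(ach, collapse = "")
  xa <- encode_seq(ach)
  out <- list()
  seen <- new.env(parent = emptyenv())
  add_seg <- function(orientation, a, b, len) {
    if (len > na || len > nb) return(invisible())
    key <- paste(orientation, a, b, sep = ":")
    prev <- get0(key, envir = seen)
    if (!is.null(prev) && prev >= len) return(invisible())
    assign(key, len, envir = seen)
    out[[key]] <<- data.frame(orientation = orientation, pos_in_a = a,
                              pos_in_b = b, length = len,
                              stringsAsFactors = FALSE)
    invisible()
  }
  if ("forward" %in% orientations) {
    sb <- paste(bch, collapse = "")
    xb <- encode_seq(bch)
    xb[xb > 4L] <- xb[xb > 4L] + length(xa)
    prs <- seed_extend_pairs(xa, xb, sa, sb, min_len, self = FALSE)
    for (r in seq_len(nrow(prs))) {
      add_seg("forward", (prs$i[r] - 1L) %% na, (prs$j[r] - 1L) %% nb,
              prs$len[r])
    }
  }
  if ("inverted" %in% orientations) {
    mb <- length(bch)
    ych <- rev(comp_chars(bch))
    sy <- paste(ych, collapse = "")
    yb <- comp_code(rev(encode_seq(bch)), shift = length(xa) + mb)
    prs <- seed_extend_pairs(xa, yb, sa, sy, min_len, self = FALSE)
    for (r in seq_len(nrow(prs))) {
      p <- mb - prs$j[r] - prs$len[r] + 2L
      add_seg("inverted", (prs$i[r] - 1L) %% na, (p - 1L) %% nb, prs$len[r])
    }
  }
  segments <- if (length(out)) do.call(rbind, out) else {
    data.frame(orientation = character(0), pos_in_a = integer(0),
               pos_in_b = integer(0), length = integer(0))
  }
  rownames(segments) <- NULL
  if (A$circ || B$circ) {
    segments <- drop_contained_pairs(segments, "pos_in_a", "pos_in_b",
                                     na, nb, allow_swap = FALSE)
  }
  segments <- segments[order(-segments$length, segments$pos_in_a), ,
                       drop = FALSE]
  ir_a <- IRanges::reduce(hit_ranges(segments$pos_in_a, segments$length, na))
  ir_b <- IRanges::reduce(hit_ranges(segments$pos_in_b, segments$length, nb))
  list(segments = segments,
       n_sites_a = length(ir_a),
       n_sites_b = length(ir_b),
       total_shared_nt = sum(IRanges::width(ir_a)))
}
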