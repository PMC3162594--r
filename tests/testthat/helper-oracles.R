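# Independent oracles used to check the package implementations.

# Brute-force maximal-repeat oracle: for every diagonal offset, compare the
# (coded) sequence against a shifted copy of itself (forward) or of its
# reverse complement (inverted); runs of equality of length >= min_len are
# exactly the maximal pairs on that diagonal.  O(n^2), fine for n <= 2 kb.
oracle_maximal_repeats <- function(s, min_len,
                                   orientations = c("forward", "inverted")) {
  x <- gclandscape:::encode_seq(gclandscape:::seq_chars(toupper(s)))
  n <- length(x)
  out <- list()
  add <- function(o, a, b, len) {
    if (a > b) { t <- a; a <- b; b <- t }
    if (a == b) return(invisible())
    out[[paste(o, a, b, len)]] <<- data.frame(
      orientation = o, pos_a = a, pos_b = b, length = len,
      stringsAsFactors = FALSE)
  }
  if ("forward" %in% orientations) {
    for (d in seq_len(n - 1L)) {
      eq <- x[1:(n - d)] == x[(1 + d):n]
      r <- rle(eq)
      e <- cumsum(r$lengths)
      s0 <- e - r$lengths + 1L
      for (q in which(r$values & r$lengths >= min_len)) {
        add("forward", s0[q] - 1L, s0[q] + d - 1L, r$lengths[q])
      }
    }
  }
  if ("inverted" %in% orientations) {
    y <- gclandscape:::comp_code(rev(x), shift = n)
    for (t in (-(n - 1L)):(n - 1L)) {
      i0 <- max(1L, 1L - t)
      j0 <- i0 + t
      m <- min(n - i0, n - j0) + 1L
      if (m < min_len) next
      eq <- x[i0:(i0 + m - 1L)] == y[j0:(j0 + m - 1L)]
      r <- rle(eq)
      e <- cumsum(r$lengths)
      s0 <- e - r$lengths + 1L
      for (q in which(r$values & r$lengths >= min_len)) {
        i <- i0 + s0[q] - 1L
        j <- j0 + s0[q] - 1L
        len <- r$lengths[q]
        add("inverted", i - 1L, n - j - len + 1L, len)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(orientation = character(0), pos_a = integer(0),
                      pos_b = integer(0), length = integer(0)))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(df$orientation, df$pos_a, df$pos_b, df$length), , drop = FALSE]
}

hit_key <- function(df, a = "pos_a", b = "pos_b") {
  sort(paste(df$orientation, df[[a]], df[[b]], df$length))
}

# Naive parent-pointer path-sum oracle for root-to-tip distances.
oracle_root_to_tip <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  d <- vapply(seq_len(n_tip), function(tip) {
    tot <- 0
    node <- tip
    while (node != root) {
      tot <- tot + elen[node]
      node <- parent[node]
    }
    tot
  }, numeric(1))
  stats::setNames(d, tree$tip.label)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
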