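# Internal helpers shared across modules.

# IUPAC nucleotide alphabet accepted on ingest; GC statistics only ever
# count the unambiguous subset.
IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#'
#' @param seq A single nucleotide string (IUPAC alphabet).
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Complement of a character vector of bases (vectorised, keeps ambiguity).
comp_chars <- function(x) {
  chartr("ACGTURYSWKMBDHVN", "TGCAAYRSWMKVHDBN", x)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Encode bases as integers; A/C/G/T -> 1:4, every other character gets a
# unique code > 4 so it never matches anything (including itself elsewhere).
encode_seq <- function(chars) {
  code <- match(chars, c("A", "C", "G", "T"))
  bad <- which(is.na(code))
  if (length(bad)) code[bad] <- 4L + seq_along(bad)
  code
}

# Format a fraction as a fixed-precision percentage string for TSV output.
fmt_pct <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

assert_scalar_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  }
}
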