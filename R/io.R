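# Format readers and writers: GenBank / FASTA in, Newick in, BED and TSV out.

#' Read a genome record from GenBank or FASTA
#'
#' GenBank input yields a fully annotated [genome_record()]; FASTA input
#' yields a record with an empty feature list (annotation-free operations
#' such as GC content, GC skew and repeat discovery still apply).
#'
#' @param path File path.
#' @param format `"genbank"` or `"fasta"`; the default guesses from the
#'   file extension (`.gb`, `.gbk`, `.genbank` vs `.fa`, `.fasta`, `.fna`).
#' @param circular For FASTA input only: topology flag to assign (GenBank
#'   carries its own).
#' @return A [genome_record()].
#' @examples
#' gb <- generate_genome(genome_spec(length = 20000, seed = 1))
#' tf <- tempfile(fileext = ".gb")
#' write_genbank(gb$record, tf)
#' rec <- read_genome_record(tf)
#' rec$length
#' @export
read_genome_record <- function(path, format = c("auto", "genbank", "fasta"),
                               circular = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "fna", "ffn")) "fasta" else "genbank"
  }
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) == 0L) stop(path, ": empty FASTA file", call. = FALSE)
    id <- strsplit(names(ss)[1], "\\s+")[[1]][1]
    return(genome_record(id, as.character(ss[[1]]), circular = circular))
  }
  parse_genbank(readLines(path, warn = FALSE), source = path)
}

#' Read a Newick tree with branch lengths
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the
#' downstream root-to-tip machinery relies on: unique leaf names,
#' non-negative branch lengths, and a branch length on every non-root
#' edge (distances would otherwise be undefined).
#'
#' @param path Path to a Newick file (or a literal Newick string via
#'   `text`).
#' @param text Optional Newick string, used instead of `path`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) {
    ape::read.tree(text = text)
  } else {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    ape::read.tree(path)
  }
  if (is.null(tr)) stop("Newick parse error (unbalanced parentheses?)",
                        call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length)) {
    stop("every edge needs a branch length", call. = FALSE)
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  tr
}

#' Write a region partition as a BED file
#'
#' One 0-based half-open BED line per maximal run of each region class,
#' with the class in the name column, sorted by start.  Adjacent
#' same-class intervals are merged before writing; a round-trip through
#' [read_region_table()] reconstructs the partition.
#'
#' @param partition A [partition_genome()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(partition, path) {
  stopifnot(inherits(partition, "region_partition"))
  rows <- list()
  for (cls in names(partition$classes)) {
    ir <- IRanges::reduce(partition$classes[[cls]])
    if (length(ir) == 0L) next
    rows[[cls]] <- data.frame(
      chrom = partition$genome_id,
      start = IRanges::start(ir) - 1L,  # IRanges is 1-based closed
      end = IRanges::end(ir),
      name = cls,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), name = character(0))
  df <- df[order(df$start, df$end), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED region table back into a partition
#'
#' @param path BED file written by [write_region_table()].
#' @param length Genome length in nt (BED does not carry it).
#' @return A `region_partition`.
#' @export
read_region_table <- function(path, length) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name"),
                          stringsAsFactors = FALSE)
  classes <- lapply(split(df, df$name), function(d) {
    IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
  })
  all_classes <- c("protein_coding", "structural_rna", "intron",
                   "unclassified_orf", "intergenic")
  for (cls in setdiff(all_classes, names(classes))) {
    classes[[cls]] <- IRanges::IRanges()
  }
  new_region_partition(unique(df$chrom)[1] %||% "NA", length,
                       classes[all_classes])
}
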