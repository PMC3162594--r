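# Pipeline orchestration: the landscape-characterisation workflow (report
# + repeat tables + BED + shared-repeat summary) and the supermatrix +
# pruning workflow, with parameter echo and deterministic TSV output.

log_msg <- function(...) message(sprintf("[gclandscape] %s", sprintf(...)))

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.6g", x))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the landscape-characterisation workflow
#'
#' For each input genome: region partition, full landscape report
#' (region-wise GC, codon-position GC, GC skew, noncoding fraction),
#' within-genome repeat discovery and repeat coverage; when exactly two
#' genomes are given, the cross-genome shared-repeat summary is added.
#' Outputs (one `landscape.tsv` row per genome, per-genome repeat TSV +
#' BED, `shared_repeats.tsv`) are byte-identical across reruns with the
#' same inputs and parameters.
#'
#' @param inputs Character vector of GenBank/FASTA paths, or a list of
#'   [genome_record()]s.
#' @param out_dir Output directory (created if needed).
#' @param min_len Within-genome minimum repeat length (default 20).
#' @param shared_min_len Cross-genome minimum segment length (default 30).
#' @param orientations Repeat orientations to search.
#' @return Invisibly, a list with `reports` (combined `data.frame`),
#'   `repeats` (per genome) and `shared` (or `NULL`).
#' @export
run_landscape <- function(inputs, out_dir, min_len = 20L,
                          shared_min_len = 30L,
                          orientations = c("forward", "inverted")) {
  if (!length(inputs)) stop("at least one genome input required",
                            call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg("landscape: %d genome(s), min_len=%d, shared_min_len=%d",
          length(inputs), min_len, shared_min_len)
  records <- lapply(inputs, function(x) {
    if (inherits(x, "genome_record")) x else read_genome_record(x)
  })
  reports <- list()
  repeats <- list()
  for (rec in records) {
    log_msg("genome %s: %d nt", rec$id, rec$length)
    part <- partition_genome(rec)
    has_cds <- any(vapply(effective_features(rec),
                          function(f) f$kind == "protein_coding", logical(1)))
    rep_row <- landscape_report(rec, part)
    hits <- find_maximal_repeats(rec, min_len = min_len,
                                 orientations = orientations)
    rep_row$repeat_pct <- 100 * repeat_coverage(hits, rec$length)
    reports[[rec$id]] <- rep_row
    repeats[[rec$id]] <- hits
    write_tsv(hits, file.path(out_dir, sprintf("repeats_%s.tsv", rec$id)))
    bed <- data.frame(chrom = rep(rec$id, 2L * nrow(hits)),
                      start = c(hits$pos_a, hits$pos_b),
                      end = c(hits$pos_a, hits$pos_b) + rep(hits$length, 2L),
                      name = rep(hits$orientation, 2L))
    bed <- bed[order(bed$start, bed$end), , drop = FALSE]
    utils::write.table(bed, file.path(out_dir,
                                      sprintf("repeats_%s.bed", rec$id)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    write_region_table(part, file.path(out_dir,
                                       sprintf("regions_%s.bed", rec$id)))
    if (!has_cds) {
      log_msg("genome %s has no annotation: codon and region GC undefined",
              rec$id)
    }
  }
  report_df <- do.call(rbind, reports)
  rownames(report_df) <- NULL
  write_tsv(report_df, file.path(out_dir, "landscape.tsv"))
  shared <- NULL
  if (length(records) == 2L) {
    shared <- shared_repeats(records[[1]], records[[2]],
                             min_len = shared_min_len,
                             orientations = orientations)
    write_tsv(shared$segments, file.path(out_dir, "shared_repeats.tsv"))
    write_tsv(data.frame(n_sites_a = shared$n_sites_a,
                         n_sites_b = shared$n_sites_b,
                         total_shared_nt = shared$total_shared_nt),
              file.path(out_dir, "shared_summary.tsv"))
    log_msg("shared repeats: %d segments, %d/%d sites, %d nt",
            nrow(shared$segments), shared$n_sites_a, shared$n_sites_b,
            shared$total_shared_nt)
  }
  invisible(list(reports = report_df, repeats = repeats, shared = shared))
}

#' Run the supermatrix-assembly workflow
#'
#' Selects genes by taxon occupancy, concatenates them with all-gap
#' padding, applies the conserved-block column filter, and writes the
#' filtered matrix (relaxed PHYLIP) plus an occupancy report.
#'
#' @param alignments List of [gene_alignment()]s or FASTA paths.
#' @param taxa Reference taxon list; defaults to the union over genes.
#' @param threshold Occupancy threshold (default 0.7).
#' @param out_dir Output directory.
#' @param ... Passed to [filter_columns()].
#' @return Invisibly, a list with `selected`, `matrix` (unfiltered) and
#'   `filtered`.
#' @export
run_supermatrix <- function(alignments, taxa = NULL, threshold = 0.7,
                            out_dir, ...) {
  alignments <- lapply(alignments, function(a) {
    if (inherits(a, "gene_alignment")) a else read_gene_alignment(a)
  })
  taxa <- taxa %||% sort(unique(unlist(lapply(alignments, `[[`, "taxa"))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sel <- select_genes(alignments, taxa, threshold)
  log_msg("supermatrix: %d/%d genes pass occupancy >= %.0f%%",
          length(sel), length(alignments), 100 * threshold)
  if (!length(sel)) stop("no gene passes the occupancy threshold",
                         call. = FALSE)
  keep <- Filter(function(a) a$gene_name %in% sel, alignments)
  sm <- concatenate_alignments(keep, taxa)
  filt <- filter_columns(sm, ...)
  log_msg("column filter: %d -> %d columns", sm$width, filt$width)
  write_phylip(filt, file.path(out_dir, "supermatrix.phy"))
  occupancy_report(sm, file.path(out_dir, "occupancy.tsv"))
  write_tsv(data.frame(gene = sel), file.path(out_dir, "selected_genes.tsv"))
  invisible(list(selected = sel, matrix = sm, filtered = filt))
}

#' Run the root-to-tip pruning workflow
#'
#' Roots the tree on the branch leading to the given outgroup clade,
#' ranks taxa by root-to-tip distance, removes the fastest-evolving
#' ones, and writes the ranking (TSV) and the pruned tree (Newick).
#'
#' @param tree A `phylo` tree or Newick path.
#' @param outgroup Taxon labels of the outgroup clade used for rooting
#'   (`NULL` when the tree is already rooted).
#' @param drop_k,drop_names,keep Passed to [remove_fast_taxa()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `ranking`, `removed`, `tree`.
#' @export
run_prune <- function(tree, outgroup = NULL, drop_k = NULL,
                      drop_names = NULL, keep = character(0), out_dir) {
  if (is.character(tree)) tree <- read_newick(tree)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(outgroup)) tree <- root_on_clade(tree, outgroup)
  rk <- root_to_tip_distances(tree)
  write_tsv(rk, file.path(out_dir, "root_to_tip.tsv"))
  res <- list(tree = tree, removed = character(0),
              retained = tree$tip.label)
  if (!is.null(drop_k) || !is.null(drop_names)) {
    res <- remove_fast_taxa(tree, k = drop_k, names = drop_names, keep = keep)
    log_msg("pruned %d taxa: %s", length(res$removed),
            paste(res$removed, collapse = ", "))
  }
  ape::write.tree(res$tree, file.path(out_dir, "pruned.nwk"))
  invisible(list(ranking = rk, removed = res$removed, tree = res$tree))
}

#' Run the synthetic-data workflow
#'
#' Generates a genome pair with shared repeat blocks plus a tree and
#' alignment set, writing GenBank, Newick, FASTA and JSON truth tables.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed driving every generator.
#' @return Invisibly, the generator outputs.
#' @export
run_simulate <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pair <- generate_genome_pair(
    genome_spec(id = "SYNMT01", seed = seed),
    ptdna_like_spec(id = "SYNPT01", seed = seed + 1L))
  write_genbank(pair$record_a, file.path(out_dir, "SYNMT01.gb"))
  write_genbank(pair$record_b, file.path(out_dir, "SYNPT01.gb"))
  write_truth_json(pair$truth_a, file.path(out_dir, "SYNMT01.truth.json"))
  write_truth_json(pair$truth_b, file.path(out_dir, "SYNPT01.truth.json"))
  ta <- generate_tree_and_alignments(seed = seed,
                                     dir = file.path(out_dir, "alignments"))
  log_msg("simulate: wrote %s", out_dir)
  invisible(list(pair = pair, tree_set = ta))
}
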