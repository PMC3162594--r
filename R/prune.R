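# Fast-evolving-taxon removal: outgroup-clade rooting, root-to-tip
# distance ranking, and pruning with suppression of degree-2 nodes.
#
# Root-to-tip distance (the sum of branch lengths from the root to a
# leaf) is a proxy for a lineage's evolutionary rate; removing the
# longest-path taxa is the standard guard against long-branch attraction.

#' Root a tree on the branch leading to a clade
#'
#' Places the root on the edge subtending the given (monophyletic) group,
#' by default at the midpoint of that edge.  The leaf set and all
#' leaf-pair path lengths are unchanged.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param clade_taxa Taxon labels of the outgroup clade (a single taxon
#'   roots on its pendant edge).
#' @param position Fraction of the subtending edge, measured from the
#'   clade side, at which the root is placed (default 0.5).
#' @return A rooted `phylo` tree.
#' @export
root_on_clade <- function(tree, clade_taxa, position = 0.5) {
  stopifnot(inherits(tree, "phylo"))
  if (!(position >= 0 && position <= 1)) {
    stop("position must be in [0, 1]", call. = FALSE)
  }
  missing_ <- setdiff(clade_taxa, tree$tip.label)
  if (length(missing_)) {
    stop("taxa not in tree: ", paste(missing_, collapse = ", "),
         call. = FALSE)
  }
  if (length(clade_taxa) >= length(tree$tip.label)) {
    stop("clade cannot contain every taxon", call. = FALSE)
  }
  if (length(clade_taxa) == 1L) {
    node <- match(clade_taxa, tree$tip.label)
  } else {
    # Evaluate monophyly on a rooted view anchored outside the clade.
    work <- tree
    if (!ape::is.rooted(work)) {
      anchor <- setdiff(work$tip.label, clade_taxa)[1]
      work <- ape::root(work, outgroup = anchor, resolve.root = TRUE)
    }
    node <- ape::getMRCA(work, clade_taxa)
    desc <- work$tip.label[descendant_tips(work, node)]
    extras <- setdiff(desc, clade_taxa)
    if (length(extras)) {
      # The clade may be monophyletic "looking the other way" in an
      # unrooted tree; try anchoring inside the complement instead.
      comp <- setdiff(work$tip.label, clade_taxa)
      node2 <- ape::getMRCA(work, comp)
      desc2 <- work$tip.label[descendant_tips(work, node2)]
      if (setequal(desc2, comp)) {
        stop("internal rooting conflict", call. = FALSE)  # unreachable
      }
      stop("clade is not monophyletic; conflicting taxa: ",
           paste(utils::head(extras, 5L), collapse = ", "), call. = FALSE)
    }
    tree <- work
  }
  edge_i <- which(tree$edge[, 2] == node)
  if (!length(edge_i)) {
    stop("clade spans the current root; re-root on its complement",
         call. = FALSE)
  }
  phytools::reroot(tree, node,
                   position = position * tree$edge.length[edge_i])
}

descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

#' Root-to-tip distances, ranked
#'
#' Sums branch lengths along each leaf's root path and sorts taxa by
#' distance, descending (the fastest-evolving taxa first); ties are
#' broken alphabetically for determinism.
#'
#' @param tree A rooted `phylo` tree with branch lengths on all edges.
#' @return `data.frame` with columns `taxon` and `distance`, ordered by
#'   decreasing distance.
#' @export
root_to_tip_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted (see root_on_clade())", call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("every edge needs a branch length", call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  d <- ape::node.depth.edgelength(tree)[seq_len(n_tip)]
  df <- data.frame(taxon = tree$tip.label, distance = d,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$distance, df$taxon), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Remove the fastest-evolving taxa from a tree
#'
#' Either the `k` largest root-to-tip-distance taxa (after exempting any
#' `keep` taxa) or an explicit name list is removed; the pruned tree has
#' degree-2 internal nodes suppressed with branch lengths summed, so
#' path lengths among survivors are unchanged.
#'
#' @param tree A rooted `phylo` tree.
#' @param k Number of fastest taxa to drop (mutually exclusive with
#'   `names`).
#' @param names Explicit taxa to drop.
#' @param keep Taxa exempt from rank-based removal (the "all except the
#'   slowly evolving ones" semantics).
#' @return List with `tree` (pruned `phylo`), `removed` and `retained`
#'   taxon vectors.
#' @export
remove_fast_taxa <- function(tree, k = NULL, names = NULL,
                             keep = character(0)) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(k) == is.null(names)) {
    stop("give exactly one of k or names", call. = FALSE)
  }
  if (!is.null(names)) {
    unknown <- setdiff(names, tree$tip.label)
    if (length(unknown)) {
      stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    drop <- names
  } else {
    if (k >= length(tree$tip.label)) {
      stop("k must be smaller than the number of leaves", call. = FALSE)
    }
    rk <- root_to_tip_distances(tree)
    candidates <- rk$taxon[!rk$taxon %in% keep]
    drop <- utils::head(candidates, k)
  }
  pruned <- ape::drop.tip(tree, drop)
  list(tree = pruned, removed = drop,
       retained = setdiff(tree$tip.label, drop))
}
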