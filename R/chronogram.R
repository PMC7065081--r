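#' Read a time-calibrated phylogeny
#'
#' Reads a Newick tree, checks branch lengths and ultrametricity (tips
#' equidistant from the root to within `tol` times the tree depth) and
#' optionally prunes it to a set of ingroup species.  Pruning preserves
#' patristic distances among retained tips exactly (branch collapse only).
#'
#' @param path Newick file path, or a string starting with `(`.
#' @param prune_to optional character vector of tip labels to keep.
#' @param tol relative ultrametricity tolerance (default 1e-6).
#' @return an [ape::phylo] tree (rooted).
#' @export
read_chronogram <- function(path, prune_to = NULL, tol = 1e-6) {
  tree <- if (grepl("^\\s*\\(", path)) ape::read.tree(text = path)
          else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick input")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!is.null(prune_to)) {
    missing <- setdiff(prune_to, tree$tip.label)
    if (length(missing))
      stop("tip(s) not in tree: ", paste(missing, collapse = ", "))
    drop <- setdiff(tree$tip.label, prune_to)
    if (length(drop)) tree <- ape::drop.tip(tree, drop)
  }
  depths <- tree_node_heights(tree)[seq_len(ape::Ntip(tree))]
  depth <- max(depths)
  if (depth <= 0) stop("tree has zero depth")
  if (diff(range(depths)) > tol * depth)
    warning("tree is not ultrametric: tip depth range ",
            signif(diff(range(depths)), 4), " exceeds tolerance")
  tree
}

#' Node heights (distance from the root) for every node of a tree
#' @param tree an `ape::phylo` object.
#' @return numeric vector indexed by ape node id (tips first).
#' @export
tree_node_heights <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Tree depth (root-to-tip time) of an ultrametric tree
#' @param tree an `ape::phylo` object.
#' @return numeric scalar.
#' @export
tree_depth <- function(tree) max(tree_node_heights(tree)[seq_len(ape::Ntip(tree))])

# Edges ordered root-to-tip (parents before children).
preorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "cladewise")
}
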