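# Small traversal helpers shared across the package. All trees are ape
# "phylo" objects; nodes are indexed the ape way (tips 1..Ntip, internals
# Ntip+1..Ntip+Nnode).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tip indices descending from a node
#'
#' @param tree a `phylo` object
#' @param node a node index; a tip index returns itself
#' @return integer vector of tip indices
#' @keywords internal
tips_under <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  phangorn::Descendants(tree, node, type = "tips")[[1]]
}

#' Labels of tips descending from a node
#' @keywords internal
tip_labels_under <- function(tree, node) {
  tree$tip.label[tips_under(tree, node)]
}

node_parent <- function(tree, node) {
  p <- phangorn::Ancestors(tree, node, type = "parent")
  if (p == 0L) NA_integer_ else p
}

node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

node_ancestors <- function(tree, node) {
  phangorn::Ancestors(tree, node, type = "all")
}

root_node <- function(tree) ape::Ntip(tree) + 1L

#' Maximal clades whose tips all satisfy a predicate
#'
#' Walks from the root and returns every node (tips included) all of whose
#' descendant tips satisfy `is_member`, without descending further into a
#' matching clade — i.e. the maximal such clades. Polytomies are handled
#' without resolving.
#'
#' @param tree rooted `phylo`
#' @param is_member logical vector over tips (length `Ntip(tree)`)
#' @return integer vector of node indices (may include tip indices)
#' @keywords internal
maximal_clades <- function(tree, is_member) {
  ntip <- ape::Ntip(tree)
  stopifnot(length(is_member) == ntip)
  out <- integer(0)
  stack <- root_node(tree)
  while (length(stack)) {
    node <- stack[[1]]
    stack <- stack[-1]
    tips <- tips_under(tree, node)
    if (all(is_member[tips])) {
      out <- c(out, node)
    } else if (node > ntip) {
      stack <- c(stack, node_children(tree, node))
    }
  }
  out
}

#' All non-trivial bipartitions of a tree as tip-membership vectors
#'
#' Each internal edge (parent, child) contributes the tip set below the
#' child. Works for rooted and unrooted trees; the root "edge" is skipped.
#'
#' @return list of logical vectors over tips, named by internal child node
#' @keywords internal
tree_splits <- function(tree, include_trivial = FALSE) {
  ntip <- ape::Ntip(tree)
  child <- tree$edge[, 2]
  if (!include_trivial) child <- child[child > ntip]
  out <- lapply(child, function(nd) {
    v <- logical(ntip)
    v[tips_under(tree, nd)] <- TRUE
    v
  })
  names(out) <- child
  out
}

# Canonical string for a split under a fixed leaf-name order: the side not
# containing the first leaf is complemented so equal bipartitions compare
# equal regardless of orientation.
split_key <- function(membership) {
  if (membership[1]) membership <- !membership
  paste(as.integer(membership), collapse = "")
}

#' The MRCA of a set of tip labels (a single label returns the tip index)
#' @keywords internal
mrca_of <- function(tree, labels) {
  idx <- match(labels, tree$tip.label)
  if (anyNA(idx)) stop("tip label(s) not in tree: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}
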