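# Constrained topologies for the approximately-unbiased (AU) test: the
# major eukaryote clade is cut into three subclades at its top two
# bipartitions, and all 15 rooted binary arrangements of {E1, E2, E3, V}
# are written out as multifurcating leaf-set constraints — 3 "original"
# topologies with the viral group sister to the intact eukaryote clade
# and 12 "alternative" ones placing it inside.

#' Split a eukaryote clade into three subclades at its top two bipartitions
#'
#' The clade's root bipartition yields two sides; the larger side is then
#' split again, giving three subclades. Any bipartition that would cut off
#' a singleton or a pair is skipped: those tips go to the excluded list and
#' splitting continues inside the remaining side.
#'
#' @param euk_clade rooted `phylo` of the eukaryote clade (>= 9 tips after
#'   exclusions)
#' @param source_clade_id optional id recorded on the partition
#' @return a `clade_partition`: list with `E1`, `E2`, `E3` (leaf-name
#'   sets), `excluded`, `source_clade_id`
#' @export
split_top_bipartitions <- function(euk_clade, source_clade_id = NA_character_) {
  stopifnot(inherits(euk_clade, "phylo"))
  excluded <- character(0)

  # Descend from `node`, applying the skip rule, until a bipartition with
  # both sides of size >= 3 is found. Returns the two sides.
  descend <- function(node) {
    repeat {
      if (node <= ape::Ntip(euk_clade))
        stop("cannot form three subclades of size >= 3")
      kids <- node_children(euk_clade, node)
      sizes <- vapply(kids, function(k) length(tips_under(euk_clade, k)),
                      integer(1))
      ord <- order(-sizes)
      kids <- kids[ord]; sizes <- sizes[ord]
      if (length(kids) > 2L) {
        side_b_tips <- unlist(lapply(kids[-1], tip_labels_under,
                                     tree = euk_clade))
        if (length(side_b_tips) <= 2L)
          stop("cannot apply the skip rule across a polytomy")
        return(list(a_node = kids[1],
                    a = tip_labels_under(euk_clade, kids[1]),
                    b_node = NA_integer_, b = side_b_tips))
      }
      small <- kids[2]; big <- kids[1]
      if (sizes[2] <= 2L) {
        excluded <<- c(excluded, tip_labels_under(euk_clade, small))
        node <- big
        next
      }
      return(list(a_node = big, a = tip_labels_under(euk_clade, big),
                  b_node = small, b = tip_labels_under(euk_clade, small)))
    }
  }

  first <- descend(root_node(euk_clade))
  # Split the larger side next (declared choice); it must be a real node.
  if (length(first$a) >= length(first$b)) {
    to_split <- first$a_node; other <- first$b
  } else {
    to_split <- first$b_node; other <- first$a
  }
  if (is.na(to_split))
    stop("side selected for the second split is not a single clade")
  second <- descend(to_split)
  parts <- list(E1 = sort(second$a), E2 = sort(second$b), E3 = sort(other))
  if (any(vapply(parts, length, integer(1)) < 3L))
    stop("cannot form three subclades of size >= 3")
  structure(c(parts, list(excluded = sort(excluded),
                          source_clade_id = source_clade_id)),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("clade partition: |E1|=%d |E2|=%d |E3|=%d, %d excluded\n",
              length(x$E1), length(x$E2), length(x$E3), length(x$excluded)))
  invisible(x)
}

# All rooted binary trees over the given labels, built by successive leaf
# insertion (each topology is produced exactly once). Trees are nested
# two-element lists with character leaves.
rooted_shapes <- function(labels) {
  trees <- list(labels[[1]])
  for (x in labels[-1]) {
    trees <- do.call(c, lapply(trees, insert_leaf, x = x))
  }
  trees
}

insert_leaf <- function(tree, x) {
  out <- list(list(tree, x))  # attach above the current root
  if (is.list(tree)) {
    for (v in insert_leaf(tree[[1]], x))
      out <- c(out, list(list(v, tree[[2]])))
    for (v in insert_leaf(tree[[2]], x))
      out <- c(out, list(list(tree[[1]], v)))
  }
  out
}

shape_newick <- function(tree, expand) {
  if (!is.list(tree)) return(expand(tree))
  paste0("(", shape_newick(tree[[1]], expand), ",",
         shape_newick(tree[[2]], expand), ")")
}

# A topology is "original" when the viral group hangs off the root as
# sister to everything else, i.e. {E1,E2,E3} is monophyletic.
is_original_shape <- function(tree, viral_label = "V") {
  is.list(tree) &&
    (identical(tree[[1]], viral_label) || identical(tree[[2]], viral_label))
}

#' Enumerate the 15 constrained topologies over {E1, E2, E3, V}
#'
#' Generates every rooted binary arrangement of the three eukaryote
#' subclades and the viral group (15 = 5!! for four labeled leaves), each
#' written as a Newick constraint in which a group's members form a
#' multifurcation. Exactly 3 are `original` (viral group sister to the
#' monophyletic eukaryote triple) and 12 `alternative`.
#'
#' @param partition a `clade_partition` from [split_top_bipartitions()]
#' @param viral_leafset character vector of viral leaf names (disjoint
#'   from the partition)
#' @return tibble with columns label, klass, newick
#' @export
enumerate_constraints <- function(partition, viral_leafset) {
  stopifnot(inherits(partition, "clade_partition"),
            length(viral_leafset) >= 1L)
  groups <- list(E1 = partition$E1, E2 = partition$E2, E3 = partition$E3,
                 V = sort(viral_leafset))
  all_leaves <- unlist(groups)
  if (any(duplicated(all_leaves)))
    stop("overlapping leaf sets between groups")
  expand <- function(label) {
    members <- groups[[label]]
    if (length(members) == 1L) members
    else paste0("(", paste(members, collapse = ","), ")")
  }
  shapes <- rooted_shapes(c("E1", "E2", "E3", "V"))
  rows <- lapply(seq_along(shapes), function(i) {
    sh <- shapes[[i]]
    tibble::tibble(
      label = sprintf("T%02d", i),
      klass = if (is_original_shape(sh)) "original" else "alternative",
      newick = paste0(shape_newick(sh, expand), ";"))
  })
  out <- do.call(rbind, rows)
  # Stable presentation: originals first, then alternatives.
  out[order(out$klass != "original", out$label), , drop = FALSE]
}

#' Write constraint topologies to one Newick file each plus a manifest
#'
#' @param constraints tibble from [enumerate_constraints()]
#' @param dir output directory (created if needed)
#' @return path of the manifest TSV
#' @export
write_constraints <- function(constraints, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, paste0("constraint_", constraints$label, ".nwk"))
  for (i in seq_len(nrow(constraints)))
    writeLines(constraints$newick[i], files[i])
  manifest <- tibble::tibble(label = constraints$label,
                             klass = constraints$klass,
                             file = basename(files))
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest_path
}
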