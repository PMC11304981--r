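# Rooting on the bacteria/archaea split, node support evaluation, and
# transfer bootstrap expectation (TBE) from bootstrap tree sets.

#' Support thresholds for calling a clade statistically supported
#'
#' Defaults follow the usual reading for IQ-TREE dual supports: SH-aLRT
#' >= 80 together with UFB >= 95, or TBE >= 70 on the transfer-bootstrap
#' basis. Thresholds are inclusive by default (`strict = FALSE`); set
#' `strict = TRUE` for strictly-greater comparison. The canonical worked
#' example — a node with UFB = 94 and SH-aLRT = 96.8 — is unsupported
#' under either reading because its UFB falls short.
#'
#' @param sh_alrt_min,ufb_min,tbe_min percent thresholds
#' @param strict use strict `>` instead of `>=`
#' @return a `support_thresholds` list
#' @export
support_thresholds <- function(sh_alrt_min = 80, ufb_min = 95,
                               tbe_min = 70, strict = FALSE) {
  vals <- c(sh_alrt_min, ufb_min, tbe_min)
  stopifnot(all(vals >= 0 & vals <= 100))
  structure(list(sh_alrt_min = sh_alrt_min, ufb_min = ufb_min,
                 tbe_min = tbe_min, strict = strict),
            class = "support_thresholds")
}

#' Is a node statistically supported?
#'
#' @param tree a `phylo` with support labels (see [node_supports()])
#' @param node internal node index; tips are trivially supported
#' @param thresholds a [support_thresholds()] object
#' @param basis `"ufb_shalrt"` (both SH-aLRT and UFB must pass) or
#'   `"tbe"`; missing values never pass
#' @return logical
#' @export
is_supported <- function(tree, node, thresholds = support_thresholds(),
                         basis = c("ufb_shalrt", "tbe")) {
  basis <- match.arg(basis)
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(TRUE)
  sup <- node_supports(tree)
  row <- sup[sup$node == node, ]
  pass <- if (thresholds$strict) function(x, t) !is.na(x) && x > t
          else function(x, t) !is.na(x) && x >= t
  if (basis == "ufb_shalrt") {
    pass(row$sh_alrt, thresholds$sh_alrt_min) &&
      pass(row$ufb, thresholds$ufb_min)
  } else {
    pass(row$tbe, thresholds$tbe_min)
  }
}

# Supported on either basis; used for rule-critical nodes whose support
# the classifier accepts from UFB/SH-aLRT or from TBE.
is_supported_any <- function(tree, node, thresholds) {
  is_supported(tree, node, thresholds, "ufb_shalrt") ||
    is_supported(tree, node, thresholds, "tbe")
}

#' Score every edge as a candidate bacteria/archaea root
#'
#' For an edge splitting the tips into sides S1/S2, the score is the
#' larger, over the two orientations, of (fraction of all bacterial tips in
#' one side) x (fraction of all archaeal tips in the other). Non-prokaryote
#' tips do not contribute. A score of 1 is attained exactly when bacteria
#' and archaea are each entirely on opposite sides.
#'
#' @param tree `phylo` (rooted or unrooted)
#' @param ann annotation tibble covering every tip
#' @return data frame with child node, score, and per-side fractions
#' @export
score_root_edges <- function(tree, ann) {
  check_tips_annotated(tree, ann)
  a <- ann[match(tree$tip.label, ann$seq_id), ]
  is_b <- a$domain == "bacteria"
  is_a <- a$domain == "archaea"
  nb <- sum(is_b); na <- sum(is_a)
  if (nb == 0L || na == 0L)
    stop("cannot root: tree must contain both bacterial and archaeal tips")
  ntip <- ape::Ntip(tree)
  child <- tree$edge[, 2]
  rows <- lapply(child, function(nd) {
    tips <- tips_under(tree, nd)
    b1 <- sum(is_b[tips]) / nb
    a1 <- sum(is_a[tips]) / na
    s_fwd <- b1 * (1 - a1)           # bacteria below, archaea above
    s_rev <- (1 - b1) * a1           # archaea below, bacteria above
    data.frame(child = nd,
               score = max(s_fwd, s_rev),
               bacteria_side_fraction = if (s_fwd >= s_rev) b1 else 1 - b1,
               archaea_side_fraction = if (s_fwd >= s_rev) 1 - a1 else a1,
               prok_below = sum(is_b[tips]) + sum(is_a[tips]),
               n_below = length(tips))
  })
  do.call(rbind, rows)
}

#' Root a gene tree at the branch separating bacteria from archaea
#'
#' The maximal-scoring edge under [score_root_edges()] becomes the root
#' branch. Ties are broken by the most balanced prokaryote tip counts
#' across the two sides, then by the lexicographically smallest sorted
#' leaf-name set of the child side. Support labels are treated as edge
#' labels (IQ-TREE semantics) so they stay attached to the correct
#' bipartition through rerooting; when branch lengths are present the root
#' is placed at the midpoint of the chosen edge.
#'
#' @inheritParams score_root_edges
#' @return a rooted `phylo`
#' @export
root_at_prok_split <- function(tree, ann) {
  scores <- score_root_edges(tree, ann)
  a <- ann[match(tree$tip.label, ann$seq_id), ]
  total_prok <- sum(a$domain %in% c("bacteria", "archaea"))
  best <- scores[scores$score == max(scores$score), , drop = FALSE]
  if (nrow(best) > 1L) {
    imbalance <- abs(total_prok - 2 * best$prok_below)
    best <- best[imbalance == min(imbalance), , drop = FALSE]
  }
  if (nrow(best) > 1L) {
    keys <- vapply(best$child, function(nd)
      paste(sort(tip_labels_under(tree, nd)), collapse = "\r"), "")
    best <- best[order(keys)[1], , drop = FALSE]
  }
  child <- best$child[1]
  ntip <- ape::Ntip(tree)
  if (child > ntip && length(tips_under(tree, child)) == ntip)
    return(tree)  # degenerate: chosen edge is the current root edge
  out_tips <- tip_labels_under(tree, child)
  edge_len <- if (!is.null(tree$edge.length))
    tree$edge.length[match(child, tree$edge[, 2])] else NA_real_
  rooted <- ape::root(tree, outgroup = out_tips, resolve.root = TRUE,
                      edgelabel = TRUE)
  if (!is.null(rooted$edge.length) && !is.na(edge_len)) {
    root_children <- node_children(rooted, root_node(rooted))
    idx <- match(root_children, rooted$edge[, 2])
    if (length(idx) == 2L)
      rooted$edge.length[idx] <- edge_len / 2
  }
  attr(rooted, "support_order") <- attr(tree, "support_order")
  rooted
}

#' Transfer bootstrap expectation for every internal branch
#'
#' For a reference branch b with lighter-side size p (>= 2), TBE(b) =
#' 100 x (1 - mean over bootstrap trees of min_b' delta(b, b') / (p - 1)),
#' where delta is the transfer distance: the smaller, over the two
#' orientations, of the symmetric difference between b's lighter side and
#' either side of b'. All branches of each bootstrap tree — including
#' trivial single-tip ones, which cap delta at p - 1 — are searched
#' exhaustively; polytomies contribute only their resolved bipartitions.
#' For a cherry (p = 2) the value reduces to the classical Felsenstein
#' presence proportion.
#'
#' @param ref reference tree (`phylo`, rooted or unrooted)
#' @param bootstraps list of trees over the identical leaf set
#' @return data frame: `node` (internal child node in `ref`), `branch_id`
#'   (sorted lighter-side leaf names joined by `|`), `p`, `tbe` (percent),
#'   `felsenstein` (plain presence percent, for reference)
#' @export
compute_tbe <- function(ref, bootstraps) {
  stopifnot(inherits(ref, "phylo"))
  if (!length(bootstraps)) stop("no bootstrap trees supplied")
  ntip <- ape::Ntip(ref)
  leaf_order <- sort(ref$tip.label)
  for (bt in bootstraps) {
    if (!identical(sort(bt$tip.label), leaf_order))
      stop("bootstrap tree leaf set differs from reference")
  }
  ref_splits <- tree_splits(ref)
  # Express bootstrap splits in the reference tip order.
  boot_splits <- lapply(bootstraps, function(bt) {
    perm <- match(ref$tip.label, bt$tip.label)
    sp <- tree_splits(bt, include_trivial = TRUE)
    lapply(sp, function(v) v[perm])
  })
  rows <- lapply(names(ref_splits), function(nd) {
    side <- ref_splits[[nd]]
    if (sum(side) > ntip / 2) side <- !side
    p <- sum(side)
    if (p < 2L) return(NULL)
    key <- split_key(side)
    dists <- vapply(boot_splits, function(splits) {
      min(vapply(splits, function(b) {
        d1 <- sum(side != b)
        min(d1, ntip - d1)
      }, numeric(1)))
    }, numeric(1))
    present <- vapply(boot_splits, function(splits) {
      any(vapply(splits, function(b) split_key(b) == key, logical(1)))
    }, logical(1))
    data.frame(node = as.integer(nd),
               branch_id = paste(sort(ref$tip.label[side]), collapse = "|"),
               p = p,
               tbe = 100 * (1 - mean(dists) / (p - 1)),
               felsenstein = 100 * mean(present))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  # A rooted tree's two root edges describe the same bipartition; report
  # each branch once.
  out[!duplicated(out$branch_id), , drop = FALSE]
}

#' Attach TBE values to a tree for support evaluation
#'
#' Stores per-internal-node TBE (from [compute_tbe()]) in `tree$tbe` so
#' that [node_supports()] and [is_supported()] can use the `"tbe"` basis.
#'
#' @export
attach_tbe <- function(tree, tbe_table) {
  ntip <- ape::Ntip(tree)
  tbe <- rep(NA_real_, tree$Nnode)
  idx <- tbe_table$node - ntip
  ok <- idx >= 1 & idx <= tree$Nnode
  tbe[idx[ok]] <- tbe_table$tbe[ok]
  tree$tbe <- tbe
  tree
}

#' Write per-branch TBE as TSV
#' @export
write_tbe <- function(tbe_table, path) {
  utils::write.table(tbe_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
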