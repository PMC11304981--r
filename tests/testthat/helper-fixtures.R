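# Shared fixtures, built in code. The default scaffold is built once per
# test run; simulations derive from it with per-test seeds.

the_scaffold <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_scaffold(scaffold_config(seed = 1))
    cache
  }
})

# A small annotation table for hand-built trees: labels starting with
# B/A/E/O/V are bacteria, archaea, nuclear eukaryotes, organellar
# eukaryotes and viruses. Eukaryote supergroup is encoded as the second
# letter block, e.g. "E_sar_1".
toy_annotations <- function(labels, viral_source = "mag",
                            rich = rep(FALSE, length(labels))) {
  domain <- ifelse(startsWith(labels, "B"), "bacteria",
            ifelse(startsWith(labels, "A"), "archaea",
            ifelse(startsWith(labels, "V"), "virus", "eukaryote")))
  compartment <- ifelse(domain %in% c("bacteria", "archaea", "virus"),
                        "not_applicable",
                        ifelse(startsWith(labels, "O"), "organellar",
                               "nuclear"))
  grp <- function(lab) {
    parts <- strsplit(lab, "_", fixed = TRUE)[[1]]
    if (length(parts) >= 2) parts[2] else lab
  }
  tibble::tibble(
    seq_id = labels,
    genome_id = labels,
    domain = domain,
    compartment = compartment,
    group = vapply(labels, grp, character(1)),
    subgroup = "",
    source = ifelse(domain == "virus", viral_source, "isolate"),
    project = "",
    in_aars_rich_clade = rich)
}

# Independent transfer-distance oracle for TBE, written over label sets
# (setdiff/union) rather than membership vectors, and scanning every node
# of every bootstrap tree.
oracle_tbe <- function(ref, bootstraps) {
  all_labels <- ref$tip.label
  n <- length(all_labels)
  side_sets <- function(tree) {
    nodes <- c(seq_len(ape::Ntip(tree)),
               ape::Ntip(tree) + seq_len(tree$Nnode))
    nodes <- setdiff(nodes, ape::Ntip(tree) + 1L)  # drop the root side
    lapply(nodes, function(nd) sort(tip_labels_under(tree, nd)))
  }
  boot_sides <- lapply(bootstraps, side_sets)
  ref_nodes <- (ape::Ntip(ref) + 2L):(ape::Ntip(ref) + ref$Nnode)
  rows <- lapply(ref_nodes, function(nd) {
    side <- sort(tip_labels_under(ref, nd))
    if (length(side) > n / 2) side <- sort(setdiff(all_labels, side))
    p <- length(side)
    if (p < 2) return(NULL)
    dmin <- vapply(boot_sides, function(sides) {
      min(vapply(sides, function(s) {
        d1 <- length(setdiff(side, s)) + length(setdiff(s, side))
        min(d1, n - d1)
      }, numeric(1)))
    }, numeric(1))
    data.frame(branch_id = paste(side, collapse = "|"),
               tbe = 100 * (1 - mean(dmin) / (p - 1)))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out[!duplicated(out$branch_id), , drop = FALSE]
}

# Independent root-scoring oracle: sides computed by deleting the edge
# from an igraph representation and taking connected components.
oracle_root_scores <- function(tree, ann) {
  a <- ann[match(tree$tip.label, ann$seq_id), ]
  nb <- sum(a$domain == "bacteria")
  na <- sum(a$domain == "archaea")
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  vapply(seq_len(nrow(tree$edge)), function(i) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, as.character(tree$edge[i, ])))
    comp <- igraph::components(g2)$membership
    side1 <- as.integer(names(comp)[comp == comp[[as.character(
      tree$edge[i, 2])]]])
    tips1 <- side1[side1 <= ape::Ntip(tree)]
    b1 <- sum(a$domain[tips1] == "bacteria") / nb
    a1 <- sum(a$domain[tips1] == "archaea") / na
    max(b1 * (1 - a1), (1 - b1) * a1)
  }, numeric(1))
}

# Brute-force labeled rooted-binary-tree enumerator used as the oracle for
# the constraint generator: builds trees by recursive bipartition of the
# label set and deduplicates by canonical string.
oracle_rooted_trees <- function(labels) {
  build <- function(labs) {
    if (length(labs) == 1L) return(labs)
    out <- character(0)
    n <- length(labs)
    for (mask in 1:(2^(n - 1) - 1)) {
      sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      left <- labs[sel]; right <- labs[!sel]
      if (!length(left) || !length(right)) next
      for (l in build(left)) for (r in build(right)) {
        pair <- sort(c(l, r))
        out <- c(out, paste0("(", pair[1], ",", pair[2], ")"))
      }
    }
    unique(out)
  }
  build(sort(labels))
}
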