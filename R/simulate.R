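# Synthetic annotated gene trees with planted evolutionary events. The
# generator emulates, at desk scale, the taxon structure the classifier
# assumes: a three-domain scaffold with organellar lineages inside
# bacteria, a eukaryote radiation of named supergroups, and a viral
# subtree with an aaRS-rich subclade, onto which one of the six scenarios
# is grafted. Node supports are simulated labels, not re-estimated: the
# package tests tree interpretation, not tree inference.

#' Configuration of the taxon scaffold
#'
#' Defaults are a scaled-down emulation of a broad three-domain sampling
#' (tens of bacterial and archaeal phyla, tens of eukaryotes across
#' several supergroups): 7 bacterial phyla x 4 taxa, 5 archaeal phyla x 3,
#' 4 eukaryote supergroups x 6 nuclear taxa, 4 organellar lineages, and
#' three virus orders with an aaRS-rich subclade of 6 genomes inside the
#' largest order.
#'
#' @param n_bact_phyla,n_bact_per_phylum bacterial sampling
#' @param n_arch_phyla,n_arch_per_phylum archaeal sampling
#' @param euk_supergroups names of eukaryote supergroups (>= 3 so that
#'   LECA-wide clades are constructible)
#' @param n_euk_per_supergroup nuclear taxa per supergroup
#' @param n_organellar organellar lineages (placed inside bacteria; at
#'   most one per supergroup)
#' @param virus_orders named integer vector: genomes per virus order; the
#'   first order hosts the aaRS-rich subclade
#' @param rich_clade_size genomes inside the aaRS-rich subclade
#' @param n_rich_isolates how many rich-clade genomes are isolates (the
#'   rest are MAGs from the "tara" project)
#' @param seed integer seed controlling branch lengths
#' @export
scaffold_config <- function(n_bact_phyla = 7, n_bact_per_phylum = 4,
                            n_arch_phyla = 5, n_arch_per_phylum = 3,
                            euk_supergroups = c("Amorphea", "SAR",
                                                "Archaeplastida", "Excavata"),
                            n_euk_per_supergroup = 6,
                            n_organellar = 4,
                            virus_orders = c(Imitervirales = 10,
                                             Algavirales = 4,
                                             Pimascovirales = 4),
                            rich_clade_size = 6,
                            n_rich_isolates = 2,
                            seed = 1) {
  if (length(euk_supergroups) < 3)
    stop("at least 3 eukaryote supergroups are required")
  stopifnot(n_bact_phyla >= 1, n_arch_phyla >= 1,
            n_euk_per_supergroup >= 1, all(virus_orders >= 1),
            rich_clade_size >= 1,
            rich_clade_size <= virus_orders[[1]],
            n_organellar <= length(euk_supergroups))
  structure(as.list(environment()), class = "scaffold_config")
}

caterpillar <- function(parts) {
  if (length(parts) == 1L) return(parts[[1]])
  out <- parts[[1]]
  for (p in parts[-1]) out <- paste0("(", out, ",", p, ")")
  out
}

clade_of <- function(tips) {
  caterpillar(as.list(tips))  # already "(...)" for two or more tips
}

#' Build the species scaffold and its annotation table
#'
#' The cellular tree's root bipartition separates bacteria (plus the
#' organellar lineages they donated) from archaea plus eukaryotes. The
#' viral subtree is kept separate; gene-tree simulation grafts it
#' according to the planted scenario.
#'
#' @param cfg a [scaffold_config()]
#' @return an `aars_scaffold`: list with `cell_tree`, `viral_tree`, `ann`,
#'   newick fragments for each block, and the config
#' @export
build_scaffold <- function(cfg = scaffold_config()) {
  stopifnot(inherits(cfg, "scaffold_config"))
  sg <- cfg$euk_supergroups

  bact_tips <- lapply(seq_len(cfg$n_bact_phyla), function(i)
    sprintf("b_p%02d_t%02d", i, seq_len(cfg$n_bact_per_phylum)))
  arch_tips <- lapply(seq_len(cfg$n_arch_phyla), function(i)
    sprintf("a_p%02d_t%02d", i, seq_len(cfg$n_arch_per_phylum)))
  euk_tips <- lapply(seq_along(sg), function(i)
    sprintf("e_%s_t%02d", tolower(sg[i]), seq_len(cfg$n_euk_per_supergroup)))
  org_tips <- if (cfg$n_organellar > 0)
    sprintf("o_%s", tolower(sg[seq_len(cfg$n_organellar)])) else character(0)

  orders <- names(cfg$virus_orders)
  viral_tips <- lapply(seq_along(orders), function(i)
    sprintf("v_%s_g%02d", tolower(orders[i]),
            seq_len(cfg$virus_orders[[i]])))
  rich_tips <- viral_tips[[1]][seq_len(cfg$rich_clade_size)]

  bact_frag <- clade_of_phyla(bact_tips)
  if (length(org_tips))  # organellar lineages nest inside bacteria
    bact_frag <- paste0("(", bact_frag, ",", clade_of(org_tips), ")")
  arch_frag <- clade_of_phyla(arch_tips)
  sg_frags <- stats::setNames(lapply(euk_tips, clade_of), sg)
  euk_frag <- balanced_join(unlist(sg_frags))

  rich_frag <- clade_of(rich_tips)
  order1_rest <- setdiff(viral_tips[[1]], rich_tips)
  order_frags <- c(
    list(if (length(order1_rest))
      paste0("(", rich_frag, ",", clade_of(order1_rest), ")")
      else rich_frag),
    lapply(viral_tips[-1], clade_of))
  viral_frag <- balanced_join(unlist(order_frags))

  cell_newick <- paste0("(", bact_frag, ",(", arch_frag, ",", euk_frag,
                        "));")
  viral_newick <- paste0(viral_frag, ";")

  ann <- rbind(
    ann_rows(unlist(bact_tips), domain = "bacteria",
             compartment = "not_applicable",
             group = rep(sprintf("BactPhylum%02d", seq_len(cfg$n_bact_phyla)),
                         each = cfg$n_bact_per_phylum)),
    ann_rows(unlist(arch_tips), domain = "archaea",
             compartment = "not_applicable",
             group = rep(sprintf("ArchPhylum%02d", seq_len(cfg$n_arch_phyla)),
                         each = cfg$n_arch_per_phylum)),
    ann_rows(unlist(euk_tips), domain = "eukaryote", compartment = "nuclear",
             group = rep(sg, each = cfg$n_euk_per_supergroup)),
    if (length(org_tips))
      ann_rows(org_tips, domain = "eukaryote", compartment = "organellar",
               group = sg[seq_len(cfg$n_organellar)]),
    ann_rows(unlist(viral_tips), domain = "virus",
             compartment = "not_applicable",
             group = rep(orders, times = lengths(viral_tips)),
             source = ifelse(unlist(viral_tips) %in%
                               rich_tips[seq_len(cfg$n_rich_isolates)],
                             "isolate", "mag"),
             project = ifelse(unlist(viral_tips) %in%
                                rich_tips[seq_len(cfg$n_rich_isolates)],
                              "", "tara"),
             in_aars_rich_clade = unlist(viral_tips) %in% rich_tips))

  set.seed(cfg$seed %% .Machine$integer.max)
  cell_tree <- with_sim_lengths(parse_newick(cell_newick))
  viral_tree <- with_sim_lengths(parse_newick(viral_newick))

  structure(list(cell_tree = cell_tree, viral_tree = viral_tree,
                 ann = ann, cfg = cfg,
                 frags = list(bact = bact_frag, arch = arch_frag,
                              sg = sg_frags, euk = euk_frag,
                              viral = viral_frag),
                 tipsets = list(bact = bact_tips, arch = arch_tips,
                                euk = stats::setNames(euk_tips, sg),
                                org = org_tips, viral = viral_tips,
                                rich = rich_tips)),
            class = "aars_scaffold")
}

clade_of_phyla <- function(tip_list) {
  balanced_join(vapply(tip_list, clade_of, character(1)))
}

# Join fragments into a (roughly) balanced binary clade, so multi-block
# subclades exist at several depths.
balanced_join <- function(frags) {
  frags <- as.character(frags)
  while (length(frags) > 1L) {
    paired <- character(0)
    i <- 1L
    while (i < length(frags)) {
      paired <- c(paired, paste0("(", frags[i], ",", frags[i + 1L], ")"))
      i <- i + 2L
    }
    if (i == length(frags)) paired <- c(paired, frags[i])
    frags <- paired
  }
  frags
}

ann_rows <- function(seq_ids, domain, compartment, group,
                     subgroup = "", source = "isolate", project = "",
                     in_aars_rich_clade = FALSE) {
  tibble::tibble(seq_id = seq_ids, genome_id = seq_ids, domain = domain,
                 compartment = compartment, group = group,
                 subgroup = subgroup, source = source, project = project,
                 in_aars_rich_clade = in_aars_rich_clade)
}

with_sim_lengths <- function(tree) {
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1)
  tree
}

#' Planted ground truth for one simulated gene tree
#'
#' @param scenario one of the six scenario labels
#' @param extra_events list of extra events, each a list with `type` in
#'   `"loss"`, `"displacement"`, `"vhgt"` and type-specific fields
#'   (`n_tips` for loss, `n_intruders` for vhgt)
#' @export
sim_truth <- function(scenario, extra_events = list()) {
  stopifnot(scenario %in% scenario_levels)
  depth <- switch(scenario,
                  proto_euk_v = "pre_leca", v_to_euk = "pre_leca",
                  ancient_euk_v = "post_leca_deep",
                  other_euk_v = "post_leca_deep",
                  recent_euk_to_v = "recent", prok_v = "recent")
  structure(list(scenario = scenario, depth_class = depth,
                 extra_events = extra_events),
            class = "sim_truth")
}

#' Noise model for simulated supports and topology perturbation
#'
#' @param nni_prob probability that each of the rule-critical edges around
#'   the grafted clade receives a random NNI; perturbed nodes get
#'   low-support labels
#' @param support_high,support_low lists with `sh` and `ufb` ranges
#'   (percent) for unperturbed and perturbed nodes
#' @param seed integer seed for all randomness of one simulation
#' @export
noise_model <- function(nni_prob = 0,
                        support_high = list(sh = c(85, 100), ufb = c(96, 100)),
                        support_low = list(sh = c(20, 79), ufb = c(40, 94)),
                        seed = 1) {
  stopifnot(nni_prob >= 0, nni_prob <= 1,
            support_low$sh[2] < 80, support_low$ufb[2] < 95)
  structure(list(nni_prob = nni_prob, support_high = support_high,
                 support_low = support_low, seed = seed),
            class = "noise_model")
}

#' Simulate one annotated gene tree with a planted scenario
#'
#' The viral clade is grafted onto the cellular backbone according to the
#' planted scenario: sister to the full eukaryote radiation
#' (`proto_euk_v`), sister to a two-supergroup subclade (`ancient_euk_v`),
#' inside a single supergroup (`recent_euk_to_v`), enclosing a eukaryote
#' clade with viral tips on both flanks (`v_to_euk`), among bacteria
#' (`prok_v`), or sister to a mixed nuclear/organellar group
#' (`other_euk_v`, timing unresolvable by construction). Extra loss,
#' displacement and vHGT events prune or regraft tips. All internal nodes
#' receive high supports except those adjacent to NNI perturbations.
#'
#' @param scaffold an `aars_scaffold`
#' @param truth a [sim_truth()]
#' @param noise a [noise_model()]
#' @return list with `tree` (rooted `phylo` with support labels), `ann`
#'   (annotations restricted to the tree's tips) and `truth`
#' @export
simulate_gene_tree <- function(scaffold, truth, noise = noise_model()) {
  stopifnot(inherits(scaffold, "aars_scaffold"),
            inherits(truth, "sim_truth"))
  set.seed(noise$seed %% .Machine$integer.max)
  ts <- scaffold$tipsets
  sg <- names(ts$euk)
  if (truth$scenario %in% c("ancient_euk_v") && length(sg) < 4)
    stop("scenario needs at least 4 supergroups in the scaffold")

  # Viral tip set: the rich subclade plus two tips from the second order
  # (realistic vHGT-like mixture); extra events adjust it.
  v_tips <- c(ts$rich, ts$viral[[2]][1:2])
  displaced <- character(0)
  for (ev in truth$extra_events) {
    if (ev$type == "loss") {
      n <- ev$n_tips %||% 1L
      v_tips <- v_tips[seq_len(max(length(v_tips) - n, 3L))]
    } else if (ev$type == "vhgt") {
      n <- ev$n_intruders %||% 1L
      pool <- setdiff(unlist(ts$viral[-1]), v_tips)
      v_tips <- c(v_tips, pool[seq_len(min(n, length(pool)))])
    } else if (ev$type == "displacement") {
      displaced <- v_tips[length(v_tips)]
      v_tips <- setdiff(v_tips, displaced)
    }
  }

  sgf <- vapply(ts$euk, clade_of, character(1))
  vc <- clade_of(v_tips)
  euk_all <- function(frags) balanced_join(frags)

  backbone <- function(euk_frag, bact_frag = scaffold$frags$bact) {
    paste0("(", bact_frag, ",(", scaffold$frags$arch, ",", euk_frag, "));")
  }

  newick <- switch(
    truth$scenario,
    proto_euk_v = backbone(paste0("(", vc, ",", euk_all(sgf), ")")),
    ancient_euk_v = {
      pair <- paste0("(", sgf[[1]], ",", sgf[[2]], ")")
      rest <- euk_all(sgf[-(1:2)])
      backbone(paste0("((", vc, ",", pair, "),", rest, ")"))
    },
    recent_euk_to_v = {
      s1 <- ts$euk[[1]]
      half <- length(s1) %/% 2
      s1_mod <- paste0("((", clade_of(s1[seq_len(half)]), ",", vc, "),",
                       clade_of(s1[-seq_len(half)]), ")")
      backbone(euk_all(c(s1_mod, sgf[-1])))
    },
    v_to_euk = {
      emb <- ts$euk[[1]][1:3]           # eukaryote clade captured by viruses
      flank_b <- v_tips[1:min(5, length(v_tips) - 3)]
      flank_a <- setdiff(v_tips, flank_b)
      region <- paste0("(", clade_of(flank_a), ",(", clade_of(emb), ",",
                       clade_of(flank_b), "))")
      s1_rest <- clade_of(setdiff(ts$euk[[1]], emb))
      backbone(paste0("(", region, ",", euk_all(c(s1_rest, sgf[-1])), ")"))
    },
    prok_v = {
      host <- clade_of(ts$bact[[1]])
      bact_mod <- sub(clade_of(ts$bact[[1]]),
                      paste0("(", host, ",", vc, ")"),
                      scaffold$frags$bact, fixed = TRUE)
      backbone(euk_all(sgf), bact_frag = bact_mod)
    },
    other_euk_v = {
      if (!length(ts$org)) stop("other_euk_v needs an organellar lineage")
      # The organellar tip moves from the bacteria block into the mixed
      # sister group, making the transfer timing unresolvable.
      bact_mod <- clade_of_phyla(ts$bact)
      if (length(ts$org) > 1)
        bact_mod <- paste0("(", bact_mod, ",", clade_of(ts$org[-1]), ")")
      mixed <- paste0("(", clade_of(ts$euk[[1]][1:3]), ",",
                      ts$org[1], ")")
      s1_rest <- clade_of(setdiff(ts$euk[[1]], ts$euk[[1]][1:3]))
      backbone(paste0("((", mixed, ",", vc, "),",
                      euk_all(c(s1_rest, sgf[-1])), ")"),
               bact_frag = bact_mod)
    },
    stop("unknown scenario: ", truth$scenario))

  if (length(displaced)) {
    # Displaced copy reappears next to a eukaryote tip far from the clade.
    target <- ts$euk[[length(ts$euk)]][1]
    newick <- sub(paste0(target, ","),
                  paste0("(", target, ",", displaced, "),"),
                  paste0(sub(";$", "", newick), ";"), fixed = TRUE)
  }

  tree <- with_sim_lengths(parse_newick(newick))

  # Topology noise: each rule-critical edge around the graft receives an
  # independent NNI with probability nni_prob.
  perturbed <- integer(0)
  if (noise$nni_prob > 0) {
    v_node <- mrca_of(tree, intersect(v_tips, tree$tip.label))
    crit <- critical_edges(tree, v_node)
    for (edge_child in crit) {
      if (stats::runif(1) < noise$nni_prob) {
        res <- nni_at_edge(tree, edge_child)
        tree <- res$tree
        perturbed <- c(perturbed, res$touched)
      }
    }
  }

  tree <- assign_sim_supports(tree, noise, perturbed)
  ann <- scaffold$ann[scaffold$ann$seq_id %in% tree$tip.label, ]
  list(tree = tree, ann = ann, truth = truth)
}

# Internal edges whose child is the grafted clade's parent, grandparent,
# or sister: the nodes the classification rules read.
critical_edges <- function(tree, v_node) {
  out <- integer(0)
  p <- node_parent(tree, v_node)
  if (!is.na(p)) {
    sib <- setdiff(node_children(tree, p), v_node)
    out <- c(out, p, sib[sib > ape::Ntip(tree)])
    g <- node_parent(tree, p)
    if (!is.na(g)) out <- c(out, g)
  }
  root <- root_node(tree)
  unique(out[out != root])
}

# One nearest-neighbour interchange across the edge above `child`
# (child must be internal): a random child of `child` is swapped with a
# random sibling of `child`. Returns the new tree plus the node numbers
# whose subtendng clades changed.
nni_at_edge <- function(tree, child) {
  ntip <- ape::Ntip(tree)
  stopifnot(child > ntip)
  parent <- node_parent(tree, child)
  if (is.na(parent)) return(list(tree = tree, touched = integer(0)))
  kids <- node_children(tree, child)
  sibs <- setdiff(node_children(tree, parent), child)
  if (!length(kids) || !length(sibs))
    return(list(tree = tree, touched = integer(0)))
  c1 <- kids[sample.int(length(kids), 1)]
  s1 <- sibs[sample.int(length(sibs), 1)]
  e_c <- which(tree$edge[, 2] == c1)
  e_s <- which(tree$edge[, 2] == s1)
  tree$edge[e_c, 1] <- parent
  tree$edge[e_s, 1] <- child
  tree <- ape::reorder.phylo(tree, "cladewise")
  list(tree = tree, touched = c(parent, child))
}

assign_sim_supports <- function(tree, noise, perturbed = integer(0)) {
  n <- tree$Nnode
  ntip <- ape::Ntip(tree)
  sh <- stats::runif(n, noise$support_high$sh[1], noise$support_high$sh[2])
  ufb <- stats::runif(n, noise$support_high$ufb[1], noise$support_high$ufb[2])
  low <- unique(perturbed) - ntip
  low <- low[low >= 1 & low <= n]
  if (length(low)) {
    sh[low] <- stats::runif(length(low), noise$support_low$sh[1],
                            noise$support_low$sh[2])
    ufb[low] <- stats::runif(length(low), noise$support_low$ufb[1],
                             noise$support_low$ufb[2])
  }
  sh[1] <- NA; ufb[1] <- NA  # the root carries no support
  set_supports(tree, round(sh, 1), round(ufb, 1))
}

#' Simulate a bootstrap tree set by random NNI perturbation
#'
#' Each replicate copies the input tree and gives each internal edge an
#' independent NNI with probability `perturb_prob`; the leaf set never
#' changes. With `perturb_prob = 0` every replicate equals the input and
#' every branch has TBE (and Felsenstein) support 100.
#'
#' @param tree a `phylo` with >= 4 leaves
#' @param n_reps number of replicates (> 0)
#' @param perturb_prob per-edge NNI probability
#' @param seed integer seed
#' @return list of `phylo` trees
#' @export
simulate_bootstrap_set <- function(tree, n_reps, perturb_prob = 0.1,
                                   seed = 1) {
  stopifnot(inherits(tree, "phylo"), ape::Ntip(tree) >= 4)
  if (n_reps <= 0) stop("n_reps must be positive")
  set.seed(seed %% .Machine$integer.max)
  ntip <- ape::Ntip(tree)
  lapply(seq_len(n_reps), function(i) {
    t <- tree
    m <- sum(t$edge[, 2] > ntip)
    hit <- stats::runif(m) < perturb_prob
    for (j in which(hit)) {
      internal_children <- t$edge[t$edge[, 2] > ntip, 2]
      if (j > length(internal_children)) next
      t <- nni_at_edge(t, internal_children[j])$tree
    }
    t
  })
}
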