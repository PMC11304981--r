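# Analyses inside the viral clades: virus-to-virus HGT (vHGT) intruders,
# displacement of vertically inherited aaRSs by cellular homologs, and
# per-genome aaRS richness with gene-loss reporting.

#' Detect candidate virus-to-virus transfers inside viral clades
#'
#' Within each viral clade whose dominant group reaches `majority_min`,
#' every minority tip becomes a vHGT candidate with the dominant group as
#' the putative donor. The grouping label combines the virus order with
#' the aaRS-rich-clade flag, so a lone sequence from outside the aaRS-rich
#' clade intruding into a rich-clade-dominated clade is reported even when
#' both belong to the same order. Clades below the majority threshold are
#' ambiguous and skipped.
#'
#' @param clades list of `viral_clade` records (see
#'   [extract_viral_clades()])
#' @param ann annotation tibble (carries `group` and
#'   `in_aars_rich_clade`)
#' @param majority_min majority fraction required to call a donor group
#'   (default 0.7)
#' @return tibble: seq_id, seq_group, clade_id, majority_group,
#'   majority_fraction
#' @export
detect_vhgt <- function(clades, ann, majority_min = 0.7) {
  rows <- lapply(clades, function(cl) {
    a <- ann[match(cl$members, ann$seq_id), ]
    grp <- ifelse(a$in_aars_rich_clade, paste0(a$group, "(aaRS-rich)"),
                  a$group)
    tab <- sort(table(grp), decreasing = TRUE)
    frac <- tab[1] / length(grp)
    if (frac < majority_min) return(NULL)
    minority <- cl$members[grp != names(tab)[1]]
    if (!length(minority)) return(NULL)
    tibble::tibble(seq_id = minority,
                   seq_group = grp[grp != names(tab)[1]],
                   clade_id = cl$clade_id,
                   majority_group = names(tab)[1],
                   majority_fraction = as.numeric(frac))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(tibble::tibble(seq_id = character(0), seq_group = character(0),
                          clade_id = character(0),
                          majority_group = character(0),
                          majority_fraction = numeric(0)))
  do.call(rbind, rows)
}

#' Detect aaRS displacement against the species-tree neighbourhood
#'
#' Each genome carries a gene-context label for one aaRS class:
#' `main_viral` (the gene sits in the main viral clade of its gene tree),
#' `eukaryote_embedded` or `prokaryote_embedded`. A genome is called
#' displaced when its context differs from the majority context of its
#' `k` nearest species-tree neighbours and that majority is `main_viral`
#' — a genome whose relatives kept the vertically inherited copy while it
#' carries a cellular homolog.
#'
#' @param assignments data frame with columns genome_id, context
#' @param species_tree `phylo` whose tips are genome ids
#' @param k neighbourhood size (default 5)
#' @return tibble: genome_id, context, neighbor_majority, n_neighbors
#' @export
detect_displacement <- function(assignments, species_tree, k = 5) {
  contexts <- c("main_viral", "eukaryote_embedded", "prokaryote_embedded")
  stopifnot(all(assignments$context %in% contexts))
  missing <- setdiff(assignments$genome_id, species_tree$tip.label)
  if (length(missing))
    stop("genome(s) missing from species tree: ",
         paste(missing, collapse = ", "))
  tr <- species_tree
  if (is.null(tr$edge.length))
    tr$edge.length <- rep(1, nrow(tr$edge))
  dmat <- ape::cophenetic.phylo(tr)
  rows <- lapply(seq_len(nrow(assignments)), function(i) {
    g <- assignments$genome_id[i]
    others <- assignments[assignments$genome_id != g, , drop = FALSE]
    if (!nrow(others)) return(NULL)
    d <- dmat[g, others$genome_id]
    ord <- order(d, others$genome_id)
    nb <- others[ord[seq_len(min(k, length(ord)))], , drop = FALSE]
    tab <- sort(table(nb$context), decreasing = TRUE)
    majority <- names(tab)[1]
    if (assignments$context[i] != majority && majority == "main_viral") {
      tibble::tibble(genome_id = g, context = assignments$context[i],
                     neighbor_majority = majority, n_neighbors = nrow(nb))
    } else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(tibble::tibble(genome_id = character(0), context = character(0),
                          neighbor_majority = character(0),
                          n_neighbors = integer(0)))
  do.call(rbind, rows)
}

#' Per-genome aaRS repertoires, clade totals and loss report
#'
#' Builds each genome's set of aaRS classes from the call table, totals
#' them over a selected species-tree clade, and reports putative losses:
#' classes present in at least `loss_frac` of a clade's sister genomes but
#' absent from every genome of the focal subclade (the pattern left by a
#' relatively recent gene loss in the subclade's ancestor).
#'
#' @param calls tibble with columns genome_id, aars_class (one row per
#'   gene)
#' @param species_tree `phylo` with genome-id tips
#' @param clade_tips optional character vector selecting the clade for the
#'   summary (default: all tips)
#' @param loss_frac prevalence required among sister genomes (default 0.8)
#' @return list with `per_genome` (tibble genome_id, n_classes, classes),
#'   `clade_summary` (tibble: n_genomes, n_aars) and `losses` (tibble:
#'   node, aars_class, sister_prevalence, n_focal_genomes)
#' @export
richness_profile <- function(calls, species_tree, clade_tips = NULL,
                             loss_frac = 0.8) {
  tips <- species_tree$tip.label
  sets <- lapply(stats::setNames(tips, tips), function(g)
    sort(unique(calls$aars_class[calls$genome_id == g])))
  per_genome <- tibble::tibble(
    genome_id = tips,
    n_classes = unname(vapply(sets, length, integer(1))),
    classes = vapply(sets, paste, character(1), collapse = ","))

  clade_tips <- clade_tips %||% tips
  n_aars <- sum(calls$genome_id %in% clade_tips)
  clade_summary <- tibble::tibble(n_genomes = length(clade_tips),
                                  n_aars = n_aars)

  losses <- list()
  ntip <- ape::Ntip(species_tree)
  internals <- ntip + seq_len(species_tree$Nnode)
  for (nd in internals) {
    s <- sister_info(species_tree, nd)
    if (is.null(s) || !length(s$tips)) next
    focal <- tips[tips_under(species_tree, nd)]
    sister_genomes <- tips[s$tips]
    for (cls in unique(calls$aars_class)) {
      prev <- mean(vapply(sister_genomes, function(g) cls %in% sets[[g]],
                          logical(1)))
      absent <- !any(vapply(focal, function(g) cls %in% sets[[g]],
                            logical(1)))
      if (prev >= loss_frac && absent) {
        losses <- c(losses, list(tibble::tibble(
          node = nd, aars_class = cls, sister_prevalence = prev,
          n_focal_genomes = length(focal))))
      }
    }
  }
  losses <- if (length(losses)) do.call(rbind, losses)
            else tibble::tibble(node = integer(0), aars_class = character(0),
                                sister_prevalence = numeric(0),
                                n_focal_genomes = integer(0))
  list(per_genome = per_genome, clade_summary = clade_summary,
       losses = losses)
}
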