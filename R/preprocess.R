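# Data-reduction rules applied before tree interpretation: ANI-based MAG
# dereplication, alignment gap trimming, aaRS assignment from best hits,
# and tree-based contamination filtering.

#' Dereplicate MAGs by ANI single-linkage clustering
#'
#' Two MAGs are linked when their ANI exceeds `ani_min` AND the alignment
#' covers more than `cov_min` percent of the smaller genome (both strict
#' inequalities). Clusters are connected components of that graph. The
#' representative of a cluster is the largest genome built by the Tara
#' Oceans project; if the cluster holds none, the largest genome overall
#' (ties broken lexicographically by genome id). Reference genomes never
#' enter the clustering: each is returned as its own singleton.
#'
#' @param ani data frame with columns genome_a, genome_b, ani,
#'   coverage_smaller (percent)
#' @param meta data frame with columns genome_id, length_bp, project, kind
#'   (kind is "mag" or "reference")
#' @param ani_min,cov_min thresholds in percent (defaults 98 and 25)
#' @return tibble with columns genome_id, cluster, representative,
#'   is_representative
#' @export
dereplicate <- function(ani, meta, ani_min = 98, cov_min = 25) {
  stopifnot(all(c("genome_a", "genome_b", "ani", "coverage_smaller") %in%
                  names(ani)),
            all(c("genome_id", "length_bp", "project", "kind") %in%
                  names(meta)))
  if (any(duplicated(meta$genome_id))) stop("duplicate genome_id in meta")
  unknown <- setdiff(unique(c(ani$genome_a, ani$genome_b)), meta$genome_id)
  if (length(unknown))
    stop("genome(s) in ANI table absent from meta: ",
         paste(unknown, collapse = ", "))
  if (any(ani$genome_a == ani$genome_b)) stop("self ANI pair")

  mags <- meta$genome_id[meta$kind == "mag"]
  refs <- meta$genome_id[meta$kind == "reference"]
  keep <- ani$ani > ani_min & ani$coverage_smaller > cov_min &
    ani$genome_a %in% mags & ani$genome_b %in% mags
  g <- igraph::graph_from_data_frame(
    ani[keep, c("genome_a", "genome_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = mags))
  comp <- igraph::components(g)$membership
  clusters <- split(names(comp), comp)
  # Deterministic cluster ids: order by smallest member name.
  clusters <- clusters[order(vapply(clusters, function(x) min(x), ""))]

  pick_rep <- function(members) {
    m <- meta[match(members, meta$genome_id), , drop = FALSE]
    tara <- m[m$project == "tara", , drop = FALSE]
    pool <- if (nrow(tara)) tara else m
    pool <- pool[order(-pool$length_bp, pool$genome_id), , drop = FALSE]
    pool$genome_id[1]
  }
  rows <- lapply(seq_along(clusters), function(i) {
    members <- sort(clusters[[i]])
    rep <- pick_rep(members)
    tibble::tibble(genome_id = members,
                   cluster = sprintf("cluster_%03d", i),
                   representative = rep,
                   is_representative = members == rep)
  })
  ref_rows <- if (length(refs)) {
    refs <- sort(refs)
    tibble::tibble(genome_id = refs,
                   cluster = paste0("ref_", refs),
                   representative = refs,
                   is_representative = TRUE)
  } else NULL
  out <- do.call(rbind, c(rows, list(ref_rows)))
  tibble::as_tibble(out)
}

#' Remove gap-rich alignment columns
#'
#' A column is kept iff its gap fraction is at most `max_gap_frac`; the
#' default 0.75 drops sites gapped in more than 75% of sequences, and 0.50
#' reproduces the stringent rerun used to probe long-branch effects.
#'
#' @param msa an `aars_msa` from [parse_alignment()]
#' @param max_gap_frac maximum tolerated gap fraction per column
#' @return list with `msa` (trimmed `aars_msa`) and `kept` (0-based column
#'   indices retained, ascending)
#' @export
trim_alignment <- function(msa, max_gap_frac = 0.75) {
  stopifnot(inherits(msa, "aars_msa"))
  if (length(msa$ids) == 0L || ncol(msa$mat) == 0L) stop("empty MSA")
  gap_frac <- colMeans(msa$mat == "-")
  kept <- which(gap_frac <= max_gap_frac)
  trimmed <- structure(list(ids = msa$ids,
                            mat = msa$mat[, kept, drop = FALSE]),
                       class = "aars_msa")
  list(msa = trimmed, kept = kept - 1L)
}

# The 20 canonical aaRS classes and the description keywords that map to
# them. Both the "-yl-tRNA synthetase" and the UniProt "--tRNA ligase"
# phrasings are recognised; subtype wording (alpha subunit, class II, ...)
# is preserved in subtype_note.
aars_classes <- c("AlaRS", "ArgRS", "AsnRS", "AspRS", "CysRS", "GlnRS",
                  "GluRS", "GlyRS", "HisRS", "IleRS", "LeuRS", "LysRS",
                  "MetRS", "PheRS", "ProRS", "SerRS", "ThrRS", "TrpRS",
                  "TyrRS", "ValRS")

default_aars_keywords <- function() {
  stems <- c(
    AlaRS = "(?<!phenyl)alan(yl|ine)", ArgRS = "argin(yl|ine)",
    AsnRS = "asparagin(yl|e)", AspRS = "aspart(yl|ate|ic acid)",
    CysRS = "cystein(yl|e)", GlnRS = "glutamin(yl|e)",
    GluRS = "glutam(yl|ate|ic acid)", GlyRS = "glyc(yl|ine)",
    HisRS = "histid(yl|ine)", IleRS = "isoleuc(yl|ine)",
    LeuRS = "(?<!iso)leuc(yl|ine)", LysRS = "lys(yl|ine)",
    MetRS = "methion(yl|ine)", PheRS = "phenylalan(yl|ine)",
    ProRS = "prol(yl|ine)", SerRS = "ser(yl|ine)",
    ThrRS = "threon(yl|ine)", TrpRS = "tryptophan(yl)?",
    TyrRS = "tyros(yl|ine)", ValRS = "val(yl|ine)")
  stats::setNames(paste0(stems, "[ -]{1,3}trna\\s+(synthetase|ligase)"),
                  names(stems))
}

#' Assign aaRS classes from homology-search best hits
#'
#' A gene is called an aaRS iff its single best hit (highest bitscore; ties
#' broken by lower e-value, then lexicographic subject id) passes the
#' e-value ceiling and its description matches an aaRS keyword. Only the
#' best hit counts: an aaRS further down the hit list never rescues a
#' non-aaRS best hit.
#'
#' @param hits tibble from [parse_hits()]
#' @param evalue_max e-value ceiling (default 1e-5)
#' @param keyword_map named character vector of per-class regexes (PCRE,
#'   matched case-insensitively); defaults cover the 20 classes
#' @param genome_of optional function mapping a query id to its genome id
#'   (defaults to the query id itself)
#' @return tibble with columns gene_id, genome_id, aars_class,
#'   subtype_note, subject_id, evalue, bitscore
#' @export
assign_aars <- function(hits, evalue_max = 1e-5,
                        keyword_map = default_aars_keywords(),
                        genome_of = identity) {
  stopifnot(all(aars_classes %in% names(keyword_map)))
  if (!nrow(hits)) return(empty_aars_calls())
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$query_id), , drop = FALSE]
  calls <- lapply(seq_len(nrow(best)), function(i) {
    row <- best[i, ]
    if (row$evalue > evalue_max) return(NULL)
    desc <- tolower(row$subject_description)
    hit_class <- NA_character_
    for (cls in names(keyword_map)) {
      if (grepl(keyword_map[[cls]], desc, perl = TRUE)) { hit_class <- cls; break }
    }
    if (is.na(hit_class)) return(NULL)
    note <- character(0)
    if (grepl("alpha", desc)) note <- c(note, "alpha subunit")
    if (grepl("beta", desc)) note <- c(note, "beta subunit")
    if (grepl("class[- ]?ii\\b", desc)) note <- c(note, "class II")
    if (grepl("class[- ]?i\\b", desc)) note <- c(note, "class I")
    tibble::tibble(gene_id = row$query_id,
                   genome_id = genome_of(row$query_id),
                   aars_class = hit_class,
                   subtype_note = paste(note, collapse = "; "),
                   subject_id = row$subject_id,
                   evalue = row$evalue,
                   bitscore = row$bitscore)
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!length(calls)) return(empty_aars_calls())
  do.call(rbind, calls)
}

empty_aars_calls <- function() {
  tibble::tibble(gene_id = character(0), genome_id = character(0),
                 aars_class = character(0), subtype_note = character(0),
                 subject_id = character(0), evalue = numeric(0),
                 bitscore = numeric(0))
}

#' Flag MAG-derived viral tips as cellular contamination
#'
#' A viral tip is flagged for removal iff (a) it does not sit inside any
#' clade containing at least two viral tips (it is an isolated viral tip in
#' a cellular neighbourhood), (b) it derives from a MAG, and (c) its contig
#' carries neither a nucleocytovirus core gene nor any gene whose best hit
#' taxonomy is nucleocytovirus. Isolate-derived sequences are never
#' removed. Contigs are matched through the optional `contig_id`
#' annotation column; a MAG tip with no contig metadata is retained with a
#' warning.
#'
#' @param tree a gene tree (rooted or unrooted `phylo`)
#' @param ann annotation tibble from [parse_annotations()]
#' @param contigs data frame with columns contig_id, genome_id,
#'   has_core_gene, has_ncv_besthit_gene
#' @return character vector of seq_ids to remove
#' @export
flag_contamination <- function(tree, ann, contigs) {
  check_tips_annotated(tree, ann)
  if (any(duplicated(contigs$contig_id))) stop("duplicate contig_id")
  a <- ann[match(tree$tip.label, ann$seq_id), ]
  viral <- a$domain == "virus"
  clades <- maximal_clades(tree, viral)
  lonely <- clades[clades <= ape::Ntip(tree)]  # singleton viral clades
  flagged <- character(0)
  for (tip in lonely) {
    row <- a[tip, ]
    if (row$source != "mag") next
    contig <- if ("contig_id" %in% names(ann)) row$contig_id else NA_character_
    if (is.na(contig) || !contig %in% contigs$contig_id) {
      warning("MAG tip ", row$seq_id,
              " has no contig metadata; retained")
      next
    }
    cm <- contigs[contigs$contig_id == contig, ]
    if (!isTRUE(as.logical(cm$has_core_gene)) &&
        !isTRUE(as.logical(cm$has_ncv_besthit_gene)))
      flagged <- c(flagged, row$seq_id)
  }
  flagged
}

check_tips_annotated <- function(tree, ann) {
  missing <- setdiff(tree$tip.label, ann$seq_id)
  if (length(missing))
    stop("tip(s) without annotation: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Flag short or long-branch tips for manual-style removal
#'
#' Operationalizes the removal of putatively nonfunctional genes: tips
#' whose ungapped sequence is shorter than `min_len` residues, or whose
#' terminal branch exceeds `k` times the median tip depth of the tree.
#' Both knobs are declared defaults, not literature values.
#'
#' @param tree gene tree with branch lengths
#' @param msa optional `aars_msa` giving the sequences (for the length rule)
#' @param min_len minimum ungapped length in residues (default 200)
#' @param k long-branch multiplier on the median tip depth (default 5)
#' @return character vector of tip labels to drop
#' @export
flag_outlier_tips <- function(tree, msa = NULL, min_len = 200, k = 5) {
  out <- character(0)
  if (!is.null(msa)) {
    len <- rowSums(msa$mat != "-")
    short <- msa$ids[len < min_len]
    out <- c(out, intersect(short, tree$tip.label))
  }
  if (!is.null(tree$edge.length)) {
    ntip <- ape::Ntip(tree)
    depths <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
    tip_edge <- tree$edge.length[match(seq_len(ntip), tree$edge[, 2])]
    long <- tree$tip.label[tip_edge > k * stats::median(depths)]
    out <- c(out, long)
  }
  unique(out)
}
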