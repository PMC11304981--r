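# Extraction of eligible viral clades from a rooted annotated gene tree
# and assignment of one of six evolutionary scenarios per clade: the
# interpretive core of the pipeline.
#
# Scenario vocabulary (ordered decision rules, first match wins):
#   prok_v          HGT between prokaryotes and nucleocytoviruses
#   v_to_euk        HGT from nucleocytoviruses to eukaryotes (nested
#                   eukaryote clade inside a viral region)
#   recent_euk_to_v recent HGT from eukaryotes to nucleocytoviruses
#   proto_euk_v     HGT between proto-eukaryotes and viruses (pre-LECA)
#   ancient_euk_v   ancient HGT predating several eukaryote lineages
#   other_euk_v     eukaryotic sister context, timing unresolved

scenario_levels <- c("proto_euk_v", "ancient_euk_v", "recent_euk_to_v",
                     "v_to_euk", "other_euk_v", "prok_v")

#' Classifier parameters
#'
#' @param min_viral minimum viral tips for a MAG-only clade to be eligible
#'   (default 3; MAG singletons and pairs are ignored, isolate-containing
#'   branches of any size are eligible)
#' @param leca_supergroups_min supergroups a sister eukaryote clade must
#'   span to be read as LECA-wide (default 3)
#' @param leca_euk_fraction_min fraction of the tree's nuclear eukaryote
#'   tips the LECA-wide clade must contain (default 0.5)
#' @param ancient_supergroups_min supergroup span for the ancient scenario
#'   (default 2)
#' @param prok_frac_min fraction of cellular tips that must be prokaryotic
#'   in the smallest enclosing cellular clade for the prokaryote scenario
#'   (default 0.8; declared, not a literature value)
#' @param viral_majority_min fraction of tips above which a node counts as
#'   majority-viral in the nesting rule (default 0.5, exclusive)
#' @param thresholds a [support_thresholds()] object
#' @export
classifier_params <- function(min_viral = 3,
                              leca_supergroups_min = 3,
                              leca_euk_fraction_min = 0.5,
                              ancient_supergroups_min = 2,
                              prok_frac_min = 0.8,
                              viral_majority_min = 0.5,
                              thresholds = support_thresholds()) {
  stopifnot(ancient_supergroups_min <= leca_supergroups_min)
  structure(list(min_viral = min_viral,
                 leca_supergroups_min = leca_supergroups_min,
                 leca_euk_fraction_min = leca_euk_fraction_min,
                 ancient_supergroups_min = ancient_supergroups_min,
                 prok_frac_min = prok_frac_min,
                 viral_majority_min = viral_majority_min,
                 thresholds = thresholds),
            class = "classifier_params")
}

#' Extract maximal all-viral clades from a rooted gene tree
#'
#' Returns every maximal clade (tips included) whose tips are exclusively
#' viral. A clade is eligible for scenario classification when it holds at
#' least `min_viral` sequences or contains an isolate-derived sequence
#' (lone isolates mirror named single-virus branches; MAG singletons and
#' pairs are treated as potential contamination and skipped).
#'
#' @param tree rooted `phylo`
#' @param ann annotation tibble covering every tip
#' @param params [classifier_params()]
#' @return list of `viral_clade` records (clade_id, node, members,
#'   n_viral, order_composition, contains_isolate, eligible)
#' @export
extract_viral_clades <- function(tree, ann, params = classifier_params()) {
  check_tips_annotated(tree, ann)
  a <- ann[match(tree$tip.label, ann$seq_id), ]
  viral <- a$domain == "virus"
  nodes <- maximal_clades(tree, viral)
  if (!length(nodes)) return(list())
  recs <- lapply(nodes, function(nd) {
    tips <- tips_under(tree, nd)
    members <- sort(tree$tip.label[tips])
    orders <- table(a$group[tips])
    contains_isolate <- any(a$source[tips] == "isolate")
    list(node = nd,
         members = members,
         n_viral = length(tips),
         order_composition = stats::setNames(as.integer(orders),
                                             names(orders)),
         contains_isolate = contains_isolate,
         eligible = length(tips) >= params$min_viral || contains_isolate)
  })
  # Deterministic ordering and ids, independent of tip order.
  keys <- vapply(recs, function(r) paste(r$members, collapse = "\r"), "")
  recs <- recs[order(keys)]
  for (i in seq_along(recs)) {
    recs[[i]]$clade_id <- sprintf("C%02d", i)
    class(recs[[i]]) <- "viral_clade"
  }
  recs
}

#' @export
print.viral_clade <- function(x, ...) {
  cat(sprintf("viral clade %s: %d tips (%s)%s\n", x$clade_id, x$n_viral,
              paste(names(x$order_composition), x$order_composition,
                    sep = ":", collapse = ", "),
              if (x$eligible) "" else " [ineligible]"))
  invisible(x)
}

# Per-tip annotation context reused by the rules.
classifier_context <- function(tree, ann) {
  a <- ann[match(tree$tip.label, ann$seq_id), ]
  list(a = a,
       viral = a$domain == "virus",
       cellular = a$domain != "virus",
       prok = a$domain %in% c("bacteria", "archaea"),
       nuc_euk = a$domain == "eukaryote" & a$compartment == "nuclear",
       org_euk = a$domain == "eukaryote" & a$compartment == "organellar",
       n_nuc_euk = sum(a$domain == "eukaryote" & a$compartment == "nuclear"))
}

supergroups_of <- function(ctx, tips) {
  unique(ctx$a$group[tips][ctx$nuc_euk[tips]])
}

majority_viral <- function(ctx, tree, node, params) {
  tips <- tips_under(tree, node)
  mean(ctx$viral[tips]) > params$viral_majority_min
}

#' Assign an evolutionary scenario to an eligible viral clade
#'
#' Applies the six ordered rules documented in the package vignette. The
#' support basis reports how the rule-critical nodes are supported:
#' `topology_ufb_shalrt` when every critical node passes the dual
#' SH-aLRT/UFB thresholds, else `topology_tbe` when all pass on TBE, else
#' `topology_only`.
#'
#' @param tree rooted `phylo` with support labels
#' @param clade a `viral_clade` from [extract_viral_clades()]
#' @param ann annotation tibble
#' @param params [classifier_params()]
#' @param aars_class optional aaRS class recorded in the call
#' @return one-row tibble (aars_class, clade_id, scenario, support_basis,
#'   notes)
#' @export
classify_scenario <- function(tree, clade, ann,
                              params = classifier_params(),
                              aars_class = NA_character_) {
  if (!clade$eligible)
    stop("clade ", clade$clade_id, " is not eligible for classification")
  ctx <- classifier_context(tree, ann)
  v <- mrca_of(tree, clade$members)
  anc <- node_ancestors(tree, v)

  result <- rule_prok_v(tree, ctx, v, anc, params)
  if (is.null(result)) result <- rule_v_to_euk(tree, ctx, v, anc, params)
  if (is.null(result)) result <- rule_recent(tree, ctx, v, anc, params)
  if (is.null(result)) result <- rule_proto(tree, ctx, v, params)
  if (is.null(result)) result <- rule_ancient(tree, ctx, v, params)
  if (is.null(result)) result <- rule_other(tree, ctx, v, params)

  basis <- support_basis(tree, result$critical, params$thresholds)
  tibble::tibble(aars_class = aars_class,
                 clade_id = clade$clade_id,
                 scenario = result$scenario,
                 support_basis = basis,
                 notes = result$notes)
}

support_basis <- function(tree, critical, thresholds) {
  critical <- unique(critical[!is.na(critical)])
  if (all(vapply(critical, function(nd)
        is_supported(tree, nd, thresholds, "ufb_shalrt"), logical(1))))
    return("topology_ufb_shalrt")
  if (all(vapply(critical, function(nd)
        is_supported(tree, nd, thresholds, "tbe"), logical(1))))
    return("topology_tbe")
  "topology_only"
}

# Rule 1: the smallest clade properly containing the viral clade together
# with at least one cellular tip is dominated by prokaryotes.
rule_prok_v <- function(tree, ctx, v, anc, params) {
  for (A in anc) {
    tips <- tips_under(tree, A)
    cell <- tips[ctx$cellular[tips]]
    if (!length(cell)) next
    frac <- mean(ctx$prok[cell])
    if (frac >= params$prok_frac_min) {
      return(list(scenario = "prok_v",
                  critical = c(v, A),
                  notes = sprintf(
                    "nearest cellular context %.0f%% prokaryotic", 100 * frac)))
    }
    return(NULL)
  }
  NULL
}

# Rule 2: a eukaryote (nuclear) tip or clade is nested inside the viral
# region: its parent is majority-viral and a further enclosing node is
# majority-viral with viral tips on the far flank too, the enclosing node
# also containing the focal viral clade.
rule_v_to_euk <- function(tree, ctx, v, anc, params) {
  euk_nodes <- maximal_clades(tree, ctx$nuc_euk)
  for (E in euk_nodes) {
    P <- node_parent(tree, E)
    if (is.na(P)) next
    if (!majority_viral(ctx, tree, P, params)) next
    p_tips <- tips_under(tree, P)
    for (Q in c(P, node_ancestors(tree, P))) {
      if (Q == P) next
      if (!(v == Q || v %in% phangorn::Descendants(tree, Q, "all"))) next
      if (!majority_viral(ctx, tree, Q, params)) next
      outer <- setdiff(tips_under(tree, Q), p_tips)
      if (!length(outer) || mean(ctx$viral[outer]) <= params$viral_majority_min)
        next
      n_e <- length(tips_under(tree, E))
      note <- if (n_e >= 2)
        sprintf("encompassing a eukaryotic clade (%d tips)", n_e)
      else "single eukaryotic tip inside viral region"
      return(list(scenario = "v_to_euk", critical = c(v, P, Q), notes = note))
    }
  }
  NULL
}

# Sister group of a node: the other children of its parent. For a root
# child with a binary root this is the opposite subtree. Returns NULL at
# the root. With a polytomous parent the siblings are pooled and treated
# as an unsupported context (no single node carries their monophyly).
sister_info <- function(tree, v) {
  p <- node_parent(tree, v)
  if (is.na(p)) return(NULL)
  sibs <- setdiff(node_children(tree, p), v)
  if (!length(sibs)) return(NULL)
  tips <- unlist(lapply(sibs, tips_under, tree = tree))
  list(nodes = sibs, tips = tips,
       node = if (length(sibs) == 1L) sibs else NA_integer_)
}

# Smallest enclosing clade whose cellular tips are all nuclear eukaryote
# and that spans >= k supergroups. Supported nodes are preferred; when no
# supported one exists the smallest topological candidate is returned
# (the call then carries a topology_only basis).
enclosing_euk_clade <- function(tree, ctx, v, anc, k, params) {
  candidates <- integer(0)
  for (A in anc) {
    tips <- tips_under(tree, A)
    cell <- tips[ctx$cellular[tips]]
    if (!length(cell)) next
    if (!all(ctx$nuc_euk[cell])) break  # larger clades only get worse
    if (length(supergroups_of(ctx, tips)) >= k) candidates <- c(candidates, A)
  }
  if (!length(candidates)) return(NA_integer_)
  supported <- candidates[vapply(candidates, function(nd)
    is_supported_any(tree, nd, params$thresholds), logical(1))]
  if (length(supported)) supported[1] else candidates[1]
}

# Rule 3: sister is a single-supergroup nuclear eukaryote group and the
# viral clade sits below a wider eukaryote radiation.
rule_recent <- function(tree, ctx, v, anc, params) {
  s <- sister_info(tree, v)
  if (is.null(s)) return(NULL)
  if (!length(s$tips) || !all(ctx$nuc_euk[s$tips])) return(NULL)
  sg <- supergroups_of(ctx, s$tips)
  if (length(sg) != 1L) return(NULL)
  A <- enclosing_euk_clade(tree, ctx, v, anc, params$ancient_supergroups_min,
                           params)
  if (is.na(A)) return(NULL)
  list(scenario = "recent_euk_to_v",
       critical = c(v, A),
       notes = sprintf("sister restricted to %s below a wider eukaryote radiation",
                       sg))
}

# Rule 4: supported viral monophyly sister to a supported LECA-wide
# eukaryote clade (>= leca_supergroups_min supergroups holding >=
# leca_euk_fraction_min of nuclear eukaryote tips), or its organellar
# variant (supported sister of organellar sequences spanning the same
# number of supergroups).
rule_proto <- function(tree, ctx, v, params) {
  s <- sister_info(tree, v)
  if (is.null(s) || is.na(s$node) || !length(s$tips)) return(NULL)
  if (!is_supported_any(tree, v, params$thresholds)) return(NULL)
  if (!is_supported_any(tree, s$node, params$thresholds)) return(NULL)
  if (all(ctx$nuc_euk[s$tips])) {
    sg <- supergroups_of(ctx, s$tips)
    frac <- sum(ctx$nuc_euk[s$tips]) / max(ctx$n_nuc_euk, 1L)
    if (length(sg) >= params$leca_supergroups_min &&
        frac >= params$leca_euk_fraction_min) {
      return(list(scenario = "proto_euk_v",
                  critical = c(v, s$node),
                  notes = sprintf(
                    "sister eukaryote clade spans %d supergroups, %.0f%% of nuclear tips",
                    length(sg), 100 * frac)))
    }
    return(NULL)
  }
  if (all(ctx$org_euk[s$tips])) {
    sg <- unique(ctx$a$group[s$tips])
    if (length(sg) >= params$leca_supergroups_min) {
      return(list(scenario = "proto_euk_v",
                  critical = c(v, s$node),
                  notes = sprintf(
                    "putatively from organelles; organellar sister spans %d supergroups",
                    length(sg))))
    }
  }
  NULL
}

# Rule 5: eukaryote sister spanning at least ancient_supergroups_min
# supergroups that misses the LECA-wide criteria (span, tip fraction or
# support).
rule_ancient <- function(tree, ctx, v, params) {
  s <- sister_info(tree, v)
  if (is.null(s) || !length(s$tips)) return(NULL)
  if (!all(ctx$nuc_euk[s$tips])) return(NULL)
  sg <- supergroups_of(ctx, s$tips)
  if (length(sg) < params$ancient_supergroups_min) return(NULL)
  list(scenario = "ancient_euk_v",
       critical = c(v, s$node),
       notes = sprintf("sister eukaryote clade spans %d supergroups (below LECA-wide criteria)",
                       length(sg)))
}

# Rule 6: eukaryotic sister context but no resolved timing; also the
# terminal fallback so that every eligible clade receives a label.
rule_other <- function(tree, ctx, v, params) {
  s <- sister_info(tree, v)
  euk_context <- !is.null(s) && length(s$tips) &&
    any(ctx$a$domain[s$tips] == "eukaryote")
  list(scenario = "other_euk_v",
       critical = c(v, if (!is.null(s)) s$node else NA_integer_),
       notes = if (euk_context) "eukaryotic sister context, timing unresolved"
               else "no clear cellular sister context")
}

#' Classify every eligible viral clade of a rooted tree
#'
#' @inheritParams classify_scenario
#' @return tibble of scenario calls, one row per eligible clade
#' @export
classify_tree <- function(tree, ann, params = classifier_params(),
                          aars_class = NA_character_) {
  clades <- extract_viral_clades(tree, ann, params)
  rows <- lapply(clades, function(cl) {
    if (!cl$eligible) return(NULL)
    classify_scenario(tree, cl, ann, params, aars_class = aars_class)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_scenario_calls())
  do.call(rbind, rows)
}

empty_scenario_calls <- function() {
  tibble::tibble(aars_class = character(0), clade_id = character(0),
                 scenario = character(0), support_basis = character(0),
                 notes = character(0))
}

#' Summarize scenario calls across aaRS classes
#'
#' Counts calls and distinct aaRS classes per scenario. The pre-LECA class
#' count unions the classes with at least one proto-eukaryotic call and
#' the classes whose nested virus-to-eukaryote calls are annotated as
#' encompassing a eukaryotic clade (the deep nested pattern whose origin
#' likewise predates LECA regardless of transfer direction).
#'
#' @param calls tibble of scenario calls
#' @return list with `per_scenario` (tibble: scenario, n_calls,
#'   n_classes), `pre_leca_classes` (character) and `n_pre_leca`
#' @export
summarize_scenarios <- function(calls) {
  per <- lapply(scenario_levels, function(sc) {
    sub <- calls[calls$scenario == sc, , drop = FALSE]
    tibble::tibble(scenario = sc, n_calls = nrow(sub),
                   n_classes = length(unique(sub$aars_class[!is.na(sub$aars_class)])))
  })
  per <- do.call(rbind, per)
  proto <- unique(calls$aars_class[calls$scenario == "proto_euk_v"])
  nested <- unique(calls$aars_class[
    calls$scenario == "v_to_euk" &
      grepl("encompassing a eukaryotic clade", calls$notes, ignore.case = TRUE)])
  pre_leca <- sort(union(proto[!is.na(proto)], nested[!is.na(nested)]))
  list(per_scenario = per,
       pre_leca_classes = pre_leca,
       n_pre_leca = length(pre_leca))
}

#' Write scenario calls as a Table-1-shaped TSV
#' @export
write_scenario_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
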