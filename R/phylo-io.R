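# Readers and writers for the formats the pipeline touches: Newick gene
# trees carrying dual "SH-aLRT/UFB" node labels (IQ-TREE's "--alrt ... -B
# ..." convention), taxon annotation TSVs, aligned protein FASTA, and
# tabular homology-search hit files.

#' Parse a Newick string into an annotated phylo tree
#'
#' Internal node labels of the form `"X/Y"` are interpreted as an
#' SH-aLRT/ultrafast-bootstrap support pair; a bare numeric label is taken
#' as UFB only. Labels are kept verbatim on the tree (`node.label`) so a
#' write/parse round trip is lossless; use [node_supports()] to get them as
#' numbers. Polytomies are accepted and preserved.
#'
#' @param text a single Newick statement terminated by `;`
#' @param swap_supports if `TRUE`, dual labels are read as `"UFB/SH-aLRT"`
#'   (for producers using the opposite order). This only affects
#'   [node_supports()], which consults the `support_order` attribute.
#' @return a `phylo` object
#' @export
#' @examples
#' tr <- parse_newick("(A:1,(B:1,C:1)80/95:2);")
#' node_supports(tr)
parse_newick <- function(text, swap_supports = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick input")
  if (!endsWith(text, ";")) stop("Newick statement must end with ';'")
  check_balanced(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  if (any(!nzchar(tree$tip.label))) stop("empty leaf name in Newick input")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) stop("duplicate leaf name(s): ", paste(dup, collapse = ", "))
  attr(tree, "support_order") <-
    if (swap_supports) c("ufb", "sh_alrt") else c("sh_alrt", "ufb")
  tree
}

# Report the first position at which parenthesis nesting breaks.
check_balanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("unbalanced '(': ", depth, " unclosed at end of input")
  invisible(TRUE)
}

#' Read one or more Newick trees from a file
#'
#' Bootstrap sets are stored one tree per line (multi-Newick).
#'
#' @param path file path
#' @param multi return a list of trees even if the file holds one
#' @export
read_newick <- function(path, multi = FALSE, swap_supports = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  trees <- lapply(lines, parse_newick, swap_supports = swap_supports)
  if (length(trees) == 1L && !multi) trees[[1]] else trees
}

#' Serialize a phylo tree to Newick
#'
#' Round-trip safe: `parse_newick(write_newick(t))` reproduces topology,
#' names, branch lengths and support labels. Trees without branch lengths
#' are written without `:` fields.
#'
#' @param tree a `phylo` object
#' @return a single Newick string
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Per-node support values parsed from node labels
#'
#' @param tree a `phylo` object, optionally carrying a `tbe` vector (one
#'   value per internal node) attached by [attach_tbe()]
#' @return data frame with columns `node`, `label`, `sh_alrt`, `ufb`,
#'   `tbe`; absent labels yield `NA` (missing, never 0)
#' @export
node_supports <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  nodes <- ntip + seq_len(nnode)
  labels <- tree$node.label %||% rep(NA_character_, nnode)
  labels[!nzchar(labels %||% "")] <- NA_character_
  ord <- attr(tree, "support_order") %||% c("sh_alrt", "ufb")
  sh <- ufb <- rep(NA_real_, nnode)
  for (i in seq_len(nnode)) {
    lab <- labels[i]
    if (is.na(lab)) next
    parts <- strsplit(lab, "/", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) == 2L && !anyNA(vals)) {
      sh[i] <- vals[match("sh_alrt", ord)]
      ufb[i] <- vals[match("ufb", ord)]
    } else if (length(vals) == 1L && !is.na(vals)) {
      ufb[i] <- vals
    }
  }
  tbe <- tree$tbe %||% rep(NA_real_, nnode)
  data.frame(node = nodes, label = labels, sh_alrt = sh, ufb = ufb,
             tbe = tbe, row.names = NULL, stringsAsFactors = FALSE)
}

#' Set dual support labels on internal nodes
#'
#' @param tree a `phylo`
#' @param sh_alrt,ufb numeric vectors over internal nodes (NA = no label)
#' @keywords internal
set_supports <- function(tree, sh_alrt, ufb) {
  stopifnot(length(sh_alrt) == tree$Nnode, length(ufb) == tree$Nnode)
  lab <- ifelse(is.na(sh_alrt) | is.na(ufb), "",
                paste0(format_support(sh_alrt), "/", format_support(ufb)))
  tree$node.label <- lab
  tree
}

format_support <- function(x) {
  out <- ifelse(is.na(x), "", format(round(x, 1), trim = TRUE))
  sub("\\.0$", "", out)
}

annotation_domains <- c("virus", "bacteria", "archaea", "eukaryote")
annotation_compartments <- c("nuclear", "organellar", "not_applicable")
annotation_sources <- c("isolate", "mag")

annotation_required_cols <- c(
  "seq_id", "genome_id", "domain", "compartment", "group", "subgroup",
  "source", "project", "in_aars_rich_clade")

#' Read and validate a taxon annotation table
#'
#' One row per sequence appearing in a gene tree. Controlled vocabularies:
#' `domain` in virus/bacteria/archaea/eukaryote; `compartment` in
#' nuclear/organellar/not_applicable (viruses must be `not_applicable`);
#' `source` in isolate/mag. `group` holds the virus order (e.g.
#' Imitervirales), eukaryote supergroup (e.g. Amorphea, SAR) or prokaryote
#' phylum. An optional `contig_id` column links each gene to its contig for
#' contamination filtering.
#'
#' @param path a TSV file path, or the literal table text
#' @return a tibble of annotations
#' @export
parse_annotations <- function(path) {
  df <- read_tsv_input(path)
  missing_cols <- setdiff(annotation_required_cols, names(df))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- function(col, vocab) {
    rows <- which(!(df[[col]] %in% vocab))
    if (length(rows))
      stop("unknown ", col, " value(s) in row(s) ",
           paste(rows, collapse = ", "), ": ",
           paste(unique(df[[col]][rows]), collapse = ", "))
  }
  bad("domain", annotation_domains)
  bad("compartment", annotation_compartments)
  bad("source", annotation_sources)
  dup <- which(duplicated(df$seq_id))
  if (length(dup))
    stop("duplicate seq_id in row(s): ", paste(dup, collapse = ", "))
  off <- which(df$domain == "virus" & df$compartment != "not_applicable")
  if (length(off))
    stop("virus rows must have compartment=not_applicable; row(s) ",
         paste(off, collapse = ", "))
  flag <- df$in_aars_rich_clade
  df$in_aars_rich_clade <- if (is.character(flag)) as.logical(flag)
                           else as.logical(as.integer(flag))
  tibble::as_tibble(df)
}

read_tsv_input <- function(path, header = TRUE) {
  is_literal <- length(path) > 1L || grepl("[\n\t]", path) ||
    !file.exists(path)
  if (is_literal) {
    con <- textConnection(paste(path, collapse = "\n"))
    on.exit(close(con))
    utils::read.delim(con, header = header, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = NA)
  } else {
    utils::read.delim(path, header = header, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = NA)
  }
}

#' Read an aligned protein FASTA into a simple MSA object
#'
#' @param path FASTA file path or literal FASTA text
#' @return an object of class `aars_msa`: list with `ids` (character) and
#'   `mat` (character matrix, one row per sequence, gap = `-`)
#' @export
parse_alignment <- function(path) {
  lines <- if (length(path) == 1L && !grepl("[\n>]", path) &&
               file.exists(path)) readLines(path, warn = FALSE)
           else strsplit(paste(path, collapse = "\n"), "\n")[[1]]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no FASTA records found")
  ids <- sub("^>\\s*", "", lines[starts])
  ids <- sub("\\s.*$", "", ids)
  ends <- c(starts[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(starts), function(i) {
    body <- if (ends[i] > starts[i]) lines[(starts[i] + 1L):ends[i]]
            else character(0)
    paste(body, collapse = "")
  }, character(1))
  seqs <- gsub("\\s", "", seqs)
  if (any(duplicated(ids))) stop("duplicate sequence ids in alignment")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat), class = "aars_msa")
}

#' @export
print.aars_msa <- function(x, ...) {
  cat("aars_msa:", length(x$ids), "sequences x", ncol(x$mat), "columns\n")
  invisible(x)
}

#' Write an MSA as aligned FASTA
#' @export
write_alignment <- function(msa, path) {
  stopifnot(inherits(msa, "aars_msa"))
  seqs <- apply(msa$mat, 1, paste, collapse = "")
  writeLines(paste0(">", msa$ids, "\n", seqs), path)
  invisible(path)
}

#' Parse a tabular homology-search hit file
#'
#' Accepts the standard 12-column tabular format, optionally with a 13th
#' subject-description column; `col_map` reassigns column positions for
#' other producers. Hits are returned sorted stably by query, then by
#' descending bitscore.
#'
#' @param path TSV path or literal text (no header)
#' @param col_map named integer vector with entries `query_id`,
#'   `subject_id`, `evalue`, `bitscore` and optionally
#'   `subject_description`
#' @return tibble with columns query_id, subject_id, evalue, bitscore,
#'   subject_description
#' @export
parse_hits <- function(path,
                       col_map = c(query_id = 1, subject_id = 2,
                                   evalue = 11, bitscore = 12,
                                   subject_description = 13)) {
  df <- read_tsv_input(path, header = FALSE)
  need <- c("query_id", "subject_id", "evalue", "bitscore")
  stopifnot(all(need %in% names(col_map)))
  get_col <- function(field) {
    idx <- col_map[[field]]
    if (is.null(idx) || is.na(idx) || idx > ncol(df)) return(NULL)
    df[[idx]]
  }
  evalue <- suppressWarnings(as.numeric(get_col("evalue")))
  if (anyNA(evalue)) stop("non-numeric evalue in hit table")
  if (any(evalue < 0)) stop("negative evalue in hit table")
  bitscore <- suppressWarnings(as.numeric(get_col("bitscore")))
  if (anyNA(bitscore)) stop("non-numeric bitscore in hit table")
  desc <- get_col("subject_description")
  out <- tibble::tibble(
    query_id = as.character(get_col("query_id")),
    subject_id = as.character(get_col("subject_id")),
    evalue = evalue,
    bitscore = bitscore,
    subject_description = if (is.null(desc)) as.character(get_col("subject_id"))
                          else as.character(desc))
  out[order(out$query_id, -out$bitscore), , drop = FALSE]
}
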