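# Packaged fixtures mirroring the published per-clade scenario table and
# headline dataset counts, plus the arithmetic report computed from them.
# The dataset-scale numbers depend on external MAG collections and are
# reproduced here only as fixtures for arithmetic and aggregation checks.

#' The published per-clade scenario table as a tibble
#'
#' One row per viral clade or branch, with the assigned scenario, its
#' support basis and the printed notes. `scenario` and `support_basis`
#' use this package's controlled vocabularies; `scenario_label` keeps the
#' printed wording.
#'
#' @return tibble with columns aars_class, clade, scenario_label,
#'   scenario, support_basis, notes
#' @export
table1_fixture <- function() {
  row <- function(cls, clade, label, support, notes = "") {
    tibble::tibble(aars_class = cls, clade = clade, scenario_label = label,
                   scenario = scenario_token(label),
                   support_basis = support_token(support), notes = notes)
  }
  out <- rbind(
    row("AlaRS", "Clade I", "Recent Euk to V", "Topology and UFB/SH-aLRT"),
    row("CysRS", "Clade I", "Ancient Euk&V", "Topology and UFB/SH-aLRT"),
    row("AspRS", "Clade I", "Proto Euk&V", "Topology and UFB/SH-aLRT"),
    row("AspRS", "Clade II", "Other Euk&V", "Topology and UFB/SH-aLRT",
        "Tupanviruses and one MAG"),
    row("GluRS", "Clade I", "Proto Euk&V", "Topology and UFB/SH-aLRT"),
    row("PheRS", "Clade I", "Proto Euk&V", "Topology and UFB/SH-aLRT",
        "Putatively from organelles"),
    row("GlyRS", "Clade I", "Proto Euk&V", "Topology and UFB/SH-aLRT"),
    row("GlyRS", "Branch I", "Prok to V", "Topology and UFB/SH-aLRT",
        "Orpheovirus"),
    row("HisRS", "Clade I", "Other Euk&V", "Topology and UFB/SH-aLRT"),
    row("HisRS", "Clade II", "V to Euk", "Topology"),
    row("HisRS", "Clade III", "Prok to V", "Topology and UFB/SH-aLRT"),
    row("IleRS", "Clade I", "Proto Euk&V", "Topology and UFB/SH-aLRT"),
    row("LysRS", "Clade I", "Proto Euk&V", "Topology and TBE"),
    row("LeuRS", "Clade I", "Proto Euk&V", "Topology and TBE"),
    row("MetRS", "Clade I", "Ancient Euk&V", "Topology and UFB/SH-aLRT"),
    row("MetRS", "Clade II", "Ancient Euk&V", "Topology and UFB/SH-aLRT"),
    row("MetRS", "Clade III", "Recent Euk to V", "Topology",
        "Klosneuvirus, hokovirus, and two MAGs"),
    row("AsnRS", "Clade I", "Ancient Euk&V", "Topology and UFB/SH-aLRT"),
    row("AsnRS", "Clade II", "Prok to V", "Topology"),
    row("ProRS", "Clade I", "Other Euk&V", "Topology"),
    row("ProRS", "Clade II", "Other Euk&V", "Topology"),
    row("GlnRS", "Clade I", "Other Euk&V", "Topology"),
    row("ArgRS", "Clade I", "Recent Euk to V", "Topology",
        "Orpheovirus and one MAG"),
    row("ArgRS", "Clade II", "Other Euk&V", "Topology"),
    row("SerRS", "Clade I", "Other Euk&V", "Topology and UFB/SH-aLRT"),
    row("SerRS", "Clade II", "Recent Euk to V", "Topology and UFB/SH-aLRT",
        "Tupanviruses and one MAG"),
    row("SerRS", "Branch I", "Recent Euk to V", "Topology and UFB/SH-aLRT",
        "Orpheovirus"),
    row("ThrRS", "Clade I", "Ancient Euk&V", "Topology"),
    row("ThrRS", "Clade II", "Recent Euk to V", "Topology",
        "Tupanviruses and one MAG"),
    row("ValRS", "Clade I", "Prok to V", "Topology and UFB/SH-aLRT",
        "Tupanviruses"),
    row("ValRS", "Clade II", "Prok to V", "Topology"),
    row("TrpRS", "Clade I", "Other Euk&V", "Topology and UFB/SH-aLRT"),
    row("TrpRS", "Clade II", "Other Euk&V", "Topology and UFB/SH-aLRT"),
    row("TrpRS", "Branch I", "Recent Euk to V", "Topology and UFB/SH-aLRT",
        "Pandoravirus salinus"),
    row("TyrRS", "Clade I", "V to Euk", "Topology and UFB/SH-aLRT",
        "Encompassing a eukaryotic clade"),
    row("TyrRS", "Clade II", "V to Euk", "Topology and UFB/SH-aLRT",
        "Encompassing a eukaryotic clade"))
  out
}

scenario_token <- function(label) {
  map <- c("Proto Euk&V" = "proto_euk_v",
           "Ancient Euk&V" = "ancient_euk_v",
           "Recent Euk to V" = "recent_euk_to_v",
           "V to Euk" = "v_to_euk",
           "Other Euk&V" = "other_euk_v",
           "Prok to V" = "prok_v")
  unname(map[label])
}

support_token <- function(label) {
  map <- c("Topology and UFB/SH-aLRT" = "topology_ufb_shalrt",
           "Topology and TBE" = "topology_tbe",
           "Topology" = "topology_only")
  unname(map[label])
}

#' Headline dataset counts as a tibble
#'
#' Totals from the full-scale analysis (not reproducible at desk scale):
#' aaRS sequences identified, genomes encoding them, the dominant-order
#' and aaRS-rich-clade totals, and the per-class counts of the three most
#' abundant classes.
#'
#' @return tibble with columns metric, value
#' @export
counts_fixture <- function() {
  tibble::tibble(
    metric = c("total_aars", "genomes_with_aars", "imitervirales_aars",
               "asnrs_count", "ilers_count", "tyrrs_count",
               "rich_clade_genomes", "rich_clade_aars",
               "nonredundant_mags", "reference_genomes"),
    value = c(780, 273, 730, 144, 125, 84, 64, 398, 3578, 224))
}

#' Arithmetic report over a counts table
#'
#' @param counts tibble from [counts_fixture()] (or an equally shaped
#'   table from a new dataset)
#' @return list of shares: `imitervirales_share` (percent, 1 decimal),
#'   `asnrs_share`, `ilers_share`, `tyrrs_share` (rounded percent) and
#'   `rich_clade_fraction_of_order`
#' @export
report_counts <- function(counts) {
  get <- function(m) counts$value[match(m, counts$metric)]
  total <- get("total_aars")
  list(
    total_aars = total,
    genomes_with_aars = get("genomes_with_aars"),
    imitervirales_share = round(100 * get("imitervirales_aars") / total, 1),
    asnrs_share = round(100 * get("asnrs_count") / total),
    ilers_share = round(100 * get("ilers_count") / total),
    tyrrs_share = round(100 * get("tyrrs_count") / total),
    rich_clade_fraction_of_order =
      get("rich_clade_aars") / get("imitervirales_aars"))
}

#' Write the packaged fixtures to TSV files
#'
#' Emits `table1.tsv` (per-clade scenario fixture) and `counts.tsv`
#' (headline counts) into `dir`. Re-reading either file reproduces the
#' in-code fixture.
#'
#' @param dir output directory
#' @return named character vector of written paths
#' @export
make_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t1 <- file.path(dir, "table1.tsv")
  ct <- file.path(dir, "counts.tsv")
  utils::write.table(table1_fixture(), t1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(counts_fixture(), ct, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(table1 = t1, counts = ct)
}
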