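# Viral clade extraction and the six-scenario classifier.

test_that("maximal viral clades are extracted with eligibility flags", {
  tr <- parse_newick("(((V_1,(V_2,(V_3,(V_4,V_5))))95/99,(B_1,B_2)),((V_6,V_7),(E_a,(A_1,V_8))));")
  ann <- toy_annotations(tr$tip.label)
  clades <- extract_viral_clades(tr, ann)
  sizes <- sort(vapply(clades, function(x) x$n_viral, integer(1)))
  expect_equal(sizes, c(1L, 2L, 5L))
  five <- clades[[which(vapply(clades, function(x) x$n_viral == 5, logical(1)))]]
  expect_true(five$eligible)
  cherry <- clades[[which(vapply(clades, function(x) x$n_viral == 2, logical(1)))]]
  expect_false(cherry$eligible)   # two MAGs are not considered
  lone <- clades[[which(vapply(clades, function(x) x$n_viral == 1, logical(1)))]]
  expect_false(lone$eligible)
})

test_that("a lone isolate inside a eukaryote clade is an eligible branch", {
  tr <- parse_newick("((B_1,B_2),((A_1,A_2),(E_am_1,(V_pando,E_am_2))));")
  ann <- toy_annotations(tr$tip.label, viral_source = "isolate")
  clades <- extract_viral_clades(tr, ann)
  expect_length(clades, 1)
  expect_true(clades[[1]]$eligible)
  expect_true(clades[[1]]$contains_isolate)
  expect_error(
    classify_scenario(tr, modifyList(clades[[1]], list(eligible = FALSE)),
                      ann),
    "not eligible")
})

test_that("unannotated tips are rejected", {
  tr <- parse_newick("((V_1,V_2),(B_1,A_1));")
  ann <- toy_annotations(tr$tip.label)[-1, ]
  expect_error(extract_viral_clades(tr, ann), "without annotation")
})

# Hand-built miniature trees reproducing the four published archetypes.
supported <- "85/96"

test_that("a supported viral clade sister to the LECA-wide eukaryote clade is proto", {
  nwk <- sprintf(paste0(
    "((B_1,B_2),((A_1,A_2),(((V_1,V_2),V_3)%s,",
    "(((E_am_1,E_am_2),(E_sar_1,E_sar_2))%s,(E_ar_1,E_ar_2)%s)%s)%s));"),
    supported, supported, supported, supported, supported)
  tr <- parse_newick(nwk)
  ann <- toy_annotations(tr$tip.label)
  calls <- classify_tree(tr, ann)
  expect_equal(calls$scenario, "proto_euk_v")
  expect_equal(calls$support_basis, "topology_ufb_shalrt")
})

test_that("a viral clade inside one supergroup below the radiation is recent", {
  # viral trio sister to an Alveolata-like pair inside a wider radiation
  nwk <- sprintf(paste0(
    "((B_1,B_2),((A_1,A_2),((((E_sar_1,E_sar_2)%s,((V_1,V_2),V_3)%s)%s,",
    "(E_sar_3,E_sar_4))%s,((E_am_1,E_am_2),(E_ar_1,E_ar_2))%s)%s));"),
    supported, supported, supported, supported, supported, supported)
  tr <- parse_newick(nwk)
  calls <- classify_tree(tr, toy_annotations(tr$tip.label))
  expect_equal(calls$scenario, "recent_euk_to_v")
})

test_that("a viral pair nested among bacteria is prok_v", {
  nwk <- sprintf(
    "(((B_1,((V_t1,V_t2,V_t3)%s,B_2)%s),(B_3,B_4)),((A_1,A_2),((E_am_1,E_am_2),(E_sar_1,E_sar_2))));",
    supported, supported)
  tr <- parse_newick(nwk)
  calls <- classify_tree(tr, toy_annotations(tr$tip.label))
  expect_equal(calls$scenario, "prok_v")
})

test_that("a eukaryote clade enclosed by two majority-viral nodes is v_to_euk", {
  nwk <- sprintf(paste0(
    "((B_1,B_2),((A_1,A_2),(((V_1,(V_2,V_3))%s,((E_fu_1,E_fu_2)%s,",
    "((V_4,V_5),(V_6,V_7))%s)%s)%s,((E_am_1,E_am_2),(E_sar_1,E_sar_2))%s)%s));"),
    supported, supported, supported, supported, supported, supported,
    supported)
  tr <- parse_newick(nwk)
  calls <- classify_tree(tr, toy_annotations(tr$tip.label))
  expect_setequal(calls$scenario, "v_to_euk")
  expect_true(any(grepl("encompassing a eukaryotic clade", calls$notes)))
})

test_that("scenario labels are exhaustive, exclusive and deterministic", {
  sc <- the_scaffold()
  for (s in scenario_levels) {
    sim <- simulate_gene_tree(sc, sim_truth(s), noise_model(seed = 99))
    calls <- classify_tree(sim$tree, sim$ann)
    expect_true(all(calls$scenario %in% scenario_levels))
    # permuting tip order leaves the calls identical
    perm <- sample(ape::Ntip(sim$tree))
    tr2 <- ape::read.tree(text = ape::write.tree(
      ape::rotateConstr(sim$tree, sim$tree$tip.label[perm])))
    attr(tr2, "support_order") <- c("sh_alrt", "ufb")
    calls2 <- classify_tree(tr2, sim$ann[sample(nrow(sim$ann)), ])
    expect_equal(calls2[order(calls2$clade_id), c("scenario", "support_basis")],
                 calls[order(calls$clade_id), c("scenario", "support_basis")])
  }
})

test_that("unsupported critical nodes downgrade proto to ancient or other", {
  nwk_tpl <- paste0(
    "((B_1,B_2),((A_1,A_2),(((V_1,V_2),V_3)%s,",
    "(((E_am_1,E_am_2),(E_sar_1,E_sar_2))85/96,(E_ar_1,E_ar_2))%s)));")
  # both critical nodes supported -> proto
  tr_hi <- parse_newick(sprintf(nwk_tpl, "85/96", "85/96"))
  ann <- toy_annotations(tr_hi$tip.label)
  expect_equal(classify_tree(tr_hi, ann)$scenario, "proto_euk_v")
  # sister support below threshold -> not proto any more
  tr_lo <- parse_newick(sprintf(nwk_tpl, "85/96", "60/80"))
  call_lo <- classify_tree(tr_lo, ann)
  expect_equal(call_lo$scenario, "ancient_euk_v")
  expect_equal(call_lo$support_basis, "topology_only")
})

test_that("TBE-only support keeps the proto call with a TBE basis", {
  nwk <- paste0(
    "((B_1,B_2),((A_1,A_2),(((V_1,V_2),V_3),",
    "(((E_am_1,E_am_2),(E_sar_1,E_sar_2)),(E_ar_1,E_ar_2)))));")
  tr <- parse_newick(nwk)
  tr$tbe <- rep(90, tr$Nnode)   # no UFB/SH-aLRT labels at all
  calls <- classify_tree(tr, toy_annotations(tr$tip.label))
  expect_equal(calls$scenario, "proto_euk_v")
  expect_equal(calls$support_basis, "topology_tbe")
})

test_that("summarize_scenarios reproduces the published aggregation", {
  t1 <- table1_fixture()
  calls <- tibble::tibble(aars_class = t1$aars_class, clade_id = t1$clade,
                          scenario = t1$scenario,
                          support_basis = t1$support_basis, notes = t1$notes)
  summ <- summarize_scenarios(calls)
  per <- summ$per_scenario
  expect_equal(per$n_classes[per$scenario == "proto_euk_v"], 7)
  expect_equal(per$n_classes[per$scenario == "ancient_euk_v"], 4)
  expect_equal(summ$n_pre_leca, 8)
  expect_true("TyrRS" %in% summ$pre_leca_classes)
  empty <- summarize_scenarios(empty_scenario_calls())
  expect_true(all(empty$per_scenario$n_calls == 0))
  expect_equal(empty$n_pre_leca, 0)
})
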