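# The synthetic-data generator: scaffold, planted scenarios, bootstrap
# perturbation and packaged fixtures.

test_that("the scaffold separates bacteria from archaea+eukaryotes at its root", {
  sc <- the_scaffold()
  tr <- sc$cell_tree
  kids <- tr$edge[tr$edge[, 1] == ape::Ntip(tr) + 1L, 2]
  sides <- lapply(kids, tip_labels_under, tree = tr)
  doms <- lapply(sides, function(s)
    unique(sc$ann$domain[match(s, sc$ann$seq_id)]))
  has_bact <- vapply(doms, function(d) "bacteria" %in% d, logical(1))
  has_arch <- vapply(doms, function(d) "archaea" %in% d, logical(1))
  expect_true(xor(has_bact[1], has_arch[1]))
  expect_true(xor(has_bact[2], has_arch[2]))
  # organellar eukaryotes ride with bacteria; nuclear ones with archaea
  bact_side <- sides[[which(has_bact)]]
  comp <- sc$ann$compartment[match(bact_side, sc$ann$seq_id)]
  expect_true(all(comp %in% c("not_applicable", "organellar")))
})

test_that("scaffold construction is deterministic and validates its config", {
  s1 <- build_scaffold(scaffold_config(seed = 7))
  s2 <- build_scaffold(scaffold_config(seed = 7))
  expect_identical(write_newick(s1$cell_tree), write_newick(s2$cell_tree))
  expect_identical(write_newick(s1$viral_tree), write_newick(s2$viral_tree))
  expect_error(scaffold_config(euk_supergroups = c("Amorphea", "SAR")),
               "at least 3")
})

test_that("every tip of a simulated tree is annotated exactly once", {
  sc <- the_scaffold()
  for (s in scenario_levels) {
    sim <- simulate_gene_tree(sc, sim_truth(s), noise_model(seed = 5))
    expect_setequal(sim$tree$tip.label, sim$ann$seq_id)
    expect_equal(anyDuplicated(sim$ann$seq_id), 0)
  }
})

test_that("planted trees are reproducible from the seed", {
  sc <- the_scaffold()
  a <- simulate_gene_tree(sc, sim_truth("ancient_euk_v"),
                          noise_model(nni_prob = 0.3, seed = 17))
  b <- simulate_gene_tree(sc, sim_truth("ancient_euk_v"),
                          noise_model(nni_prob = 0.3, seed = 17))
  expect_identical(write_newick(a$tree), write_newick(b$tree))
})

test_that("the planted v_to_euk pattern has viral tips on both flanks", {
  sc <- the_scaffold()
  sim <- simulate_gene_tree(sc, sim_truth("v_to_euk"), noise_model(seed = 3))
  ann <- sim$ann
  viral <- ann$domain[match(sim$tree$tip.label, ann$seq_id)] == "virus"
  euk_nodes <- maximal_clades(
    sim$tree, ann$domain[match(sim$tree$tip.label, ann$seq_id)] == "eukaryote" &
      ann$compartment[match(sim$tree$tip.label, ann$seq_id)] == "nuclear")
  embedded <- FALSE
  for (E in euk_nodes) {
    P <- node_parent(sim$tree, E)
    if (is.na(P)) next
    ptips <- tips_under(sim$tree, P)
    if (mean(viral[ptips]) <= 0.5) next
    G <- node_parent(sim$tree, P)
    if (is.na(G)) next
    outer <- setdiff(tips_under(sim$tree, G), ptips)
    if (length(outer) && mean(viral[outer]) > 0.5) embedded <- TRUE
  }
  expect_true(embedded)
})

test_that("simulated supports fall in the configured ranges", {
  sc <- the_scaffold()
  sim <- simulate_gene_tree(sc, sim_truth("proto_euk_v"),
                            noise_model(seed = 23))
  sup <- node_supports(sim$tree)
  sup <- sup[!is.na(sup$sh_alrt), ]
  expect_true(all(sup$sh_alrt >= 85 & sup$sh_alrt <= 100))
  expect_true(all(sup$ufb >= 96 & sup$ufb <= 100))
  expect_error(noise_model(support_low = list(sh = c(20, 79),
                                              ufb = c(40, 96))))
})

test_that("bootstrap replication: identity at zero perturbation, change at one", {
  tr <- parse_newick("((A,B),((C,D),(E,(F,G))));")
  reps0 <- simulate_bootstrap_set(tr, 10, perturb_prob = 0, seed = 1)
  key <- function(t) sort(vapply(tree_splits(t),
                                 function(v) split_key(v[order(t$tip.label)]),
                                 ""))
  expect_true(all(vapply(reps0, function(t) identical(key(t), key(tr)),
                         logical(1))))
  tb <- compute_tbe(tr, reps0)
  expect_true(all(tb$tbe == 100))

  reps1 <- simulate_bootstrap_set(tr, 30, perturb_prob = 1, seed = 2)
  changed <- vapply(reps1, function(t) !identical(key(t), key(tr)),
                    logical(1))
  expect_gt(mean(changed), 0.8)
  expect_true(all(vapply(reps1, function(t)
    setequal(t$tip.label, tr$tip.label), logical(1))))
  expect_error(simulate_bootstrap_set(tr, 0, 0.1), "positive")
})

test_that("fixture files round-trip through TSV", {
  dir <- withr::local_tempdir()
  paths <- make_fixtures(dir)
  t1 <- utils::read.delim(paths[["table1"]], na.strings = NULL)
  t1$notes[is.na(t1$notes)] <- ""
  expect_equal(nrow(t1), nrow(table1_fixture()))
  expect_identical(t1$scenario, table1_fixture()$scenario)
  expect_identical(t1$notes, table1_fixture()$notes)
  ct <- utils::read.delim(paths[["counts"]])
  expect_equal(ct$value, counts_fixture()$value)
})
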