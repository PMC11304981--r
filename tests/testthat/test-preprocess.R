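# Dereplication, trimming, aaRS assignment and contamination filtering.

mk_meta <- function(ids, len, project = "", kind = "mag") {
  tibble::tibble(genome_id = ids, length_bp = len,
                 project = rep_len(project, length(ids)),
                 kind = rep_len(kind, length(ids)))
}
mk_ani <- function(a, b, ani, cov) {
  tibble::tibble(genome_a = a, genome_b = b, ani = ani,
                 coverage_smaller = cov)
}

test_that("dereplication links pairs only above both strict thresholds", {
  meta <- mk_meta(c("M1", "M2", "M3"), c(100, 200, 300))
  cl <- dereplicate(mk_ani("M1", "M2", 99, 30), meta)
  expect_equal(sort(unique(cl$cluster[cl$genome_id %in% c("M1", "M2")])),
               unique(cl$cluster[cl$genome_id == "M1"]))
  expect_equal(cl$representative[cl$genome_id == "M1"], "M2")  # larger wins
  # coverage exactly at / below threshold adds no edge
  cl2 <- dereplicate(mk_ani("M1", "M3", 99, 25), meta)
  expect_equal(length(unique(cl2$cluster)), 3)
  # ANI exactly at threshold adds no edge either
  cl3 <- dereplicate(mk_ani("M1", "M3", 98, 90), meta)
  expect_equal(length(unique(cl3$cluster)), 3)
})

test_that("chained pairs merge into one component (brute-force oracle)", {
  meta <- mk_meta(c("M1", "M2", "M3", "M4"), c(10, 20, 30, 40))
  ani <- mk_ani(c("M1", "M2"), c("M2", "M4"), c(99, 99), c(30, 30))
  cl <- dereplicate(ani, meta)
  # oracle: transitive closure by repeated expansion of the edge list
  edges <- list(c("M1", "M2"), c("M2", "M4"))
  comp <- list("M1", "M2", "M3", "M4")
  repeat {
    merged <- FALSE
    for (e in edges) {
      i <- which(vapply(comp, function(s) e[1] %in% s, logical(1)))
      j <- which(vapply(comp, function(s) e[2] %in% s, logical(1)))
      if (i != j) {
        comp[[i]] <- union(comp[[i]], comp[[j]]); comp[[j]] <- NULL
        merged <- TRUE; break
      }
    }
    if (!merged) break
  }
  expect_equal(length(unique(cl$cluster)), length(comp))
  expect_setequal(cl$genome_id[cl$cluster == cl$cluster[cl$genome_id == "M1"]],
                  c("M1", "M2", "M4"))
})

test_that("tara project representatives beat larger non-tara genomes", {
  meta <- tibble::tibble(genome_id = c("M1", "M2"),
                         length_bp = c(500, 100),
                         project = c("", "tara"), kind = "mag")
  cl <- dereplicate(mk_ani("M1", "M2", 99, 40), meta)
  expect_equal(unique(cl$representative), "M2")
})

test_that("dereplication partitions the MAG set and is idempotent on reps", {
  set.seed(3)
  ids <- sprintf("M%02d", 1:12)
  meta <- mk_meta(ids, sample(1e4:1e6, 12))
  pairs <- t(utils::combn(ids, 2))
  sel <- sample(nrow(pairs), 8)
  ani <- mk_ani(pairs[sel, 1], pairs[sel, 2],
                runif(8, 95, 100), runif(8, 10, 60))
  cl <- dereplicate(ani, meta)
  expect_setequal(cl$genome_id, ids)                       # partition
  expect_equal(anyDuplicated(cl$genome_id), 0)
  for (cc in unique(cl$cluster)) {                          # rep is a member
    sub <- cl[cl$cluster == cc, ]
    expect_true(unique(sub$representative) %in% sub$genome_id)
  }
  reps <- cl$genome_id[cl$is_representative]
  ani_reps <- ani[ani$genome_a %in% reps & ani$genome_b %in% reps, ]
  cl2 <- dereplicate(ani_reps, meta[meta$genome_id %in% reps, ])
  expect_equal(length(unique(cl2$cluster)), length(reps))   # all singletons
})

test_that("reference genomes never merge into MAG clusters", {
  meta <- tibble::tibble(genome_id = c("M1", "R1"), length_bp = c(10, 10),
                         project = "", kind = c("mag", "reference"))
  cl <- dereplicate(mk_ani("M1", "R1", 99.9, 99), meta)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_error(dereplicate(mk_ani("M1", "MX", 99, 40), meta),
               "absent from meta")
})

test_that("gap trimming applies the strict more-than rule at both thresholds", {
  # 4 rows; column 2 has exactly 3/4 gaps
  msa <- parse_alignment(">a\nM-A\n>b\nM-A\n>c\nM-A\n>d\nMKA\n")
  kept75 <- trim_alignment(msa, 0.75)
  expect_equal(kept75$kept, c(0, 1, 2))          # 0.75 is not > 0.75
  kept50 <- trim_alignment(msa, 0.50)
  expect_equal(kept50$kept, c(0, 2))             # 0.75 > 0.50: removed
  gap_free <- parse_alignment(">a\nMKA\n>b\nMRA\n")
  expect_equal(trim_alignment(gap_free)$kept, 0:2)
  expect_identical(trim_alignment(gap_free)$msa$mat, gap_free$mat)
})

test_that("trimming matches a direct column-scan oracle and is monotone", {
  set.seed(5)
  mat <- matrix(sample(c("-", "A", "K"), 30 * 40, TRUE, c(.4, .3, .3)),
                nrow = 30)
  rownames(mat) <- sprintf("s%02d", 1:30)
  msa <- structure(list(ids = rownames(mat), mat = mat), class = "aars_msa")
  for (thr in c(0.5, 0.75)) {
    res <- trim_alignment(msa, thr)
    oracle <- which(apply(mat, 2, function(col) mean(col == "-") <= thr)) - 1L
    expect_equal(res$kept, oracle)
    # idempotence at fixed threshold
    again <- trim_alignment(res$msa, thr)
    expect_equal(ncol(again$msa$mat), ncol(res$msa$mat))
  }
  expect_true(all(trim_alignment(msa, 0.5)$kept %in%
                    trim_alignment(msa, 0.75)$kept))
  expect_error(trim_alignment(structure(list(ids = character(0),
                                             mat = matrix(character(0), 0, 0)),
                                        class = "aars_msa")), "empty")
})

hit_row <- function(q, s, e, b, desc) {
  sprintf("%s\t%s\t90\t100\t0\t0\t1\t100\t1\t100\t%g\t%g\t%s", q, s, e, b, desc)
}

test_that("aaRS assignment uses only the best hit under the e-value ceiling", {
  hits <- parse_hits(paste(
    hit_row("g1", "u1", 1e-30, 200, "asparaginyl-tRNA synthetase"),
    hit_row("g2", "u2", 1e-3, 90, "isoleucyl-tRNA synthetase"),
    hit_row("g3", "u3", 1e-50, 300, "DNA polymerase family B"),
    hit_row("g3", "u4", 1e-45, 250, "tyrosyl-tRNA synthetase"),
    hit_row("g4", "u5", 1e-25, 180, "Phenylalanine--tRNA ligase alpha subunit"),
    sep = "\n"))
  calls <- assign_aars(hits)
  expect_setequal(calls$gene_id, c("g1", "g4"))
  expect_equal(calls$aars_class[calls$gene_id == "g1"], "AsnRS")   # called
  # g2: aaRS but e-value 1e-3 fails; g3: best hit is not an aaRS
  expect_equal(calls$aars_class[calls$gene_id == "g4"], "PheRS")
  expect_match(calls$subtype_note[calls$gene_id == "g4"], "alpha")
})

test_that("keyword matching distinguishes confusable class names", {
  mk <- function(desc) assign_aars(parse_hits(hit_row("g", "u", 1e-30, 100,
                                                      desc)))$aars_class
  expect_equal(mk("glutaminyl-tRNA synthetase"), "GlnRS")
  expect_equal(mk("glutamate--tRNA ligase"), "GluRS")
  expect_equal(mk("isoleucine--tRNA ligase"), "IleRS")
  expect_equal(mk("leucyl-tRNA synthetase"), "LeuRS")
  expect_equal(mk("alanyl-tRNA synthetase"), "AlaRS")
  expect_length(assign_aars(parse_hits(hit_row("g", "u", 1e-30, 100,
                                               "hypothetical protein")))$gene_id,
                0)
})

test_that("ties on bitscore break by lower e-value then subject id", {
  hits <- parse_hits(paste(
    hit_row("g1", "zz", 1e-40, 100, "valyl-tRNA synthetase"),
    hit_row("g1", "aa", 1e-20, 100, "DNA gyrase"),
    sep = "\n"))
  calls <- assign_aars(hits)   # best = zz (lower e-value): ValRS
  expect_equal(calls$aars_class, "ValRS")
})

test_that("contamination flagging follows the three-condition rule", {
  # lone viral tip among bacteria; a 2-virus cherry elsewhere
  tr <- parse_newick("(((B_1,(B_2,V_lone)),(B_3,B_4)),((V_c1,V_c2),A_1));")
  ann <- toy_annotations(tr$tip.label)
  ann$contig_id <- ifelse(ann$domain == "virus",
                          paste0("ctg_", ann$seq_id), NA)
  contigs <- tibble::tibble(
    contig_id = paste0("ctg_", c("V_lone", "V_c1", "V_c2")),
    genome_id = c("V_lone", "V_c1", "V_c2"),
    has_core_gene = FALSE, has_ncv_besthit_gene = FALSE)
  expect_equal(flag_contamination(tr, ann, contigs), "V_lone")
  # a core gene on the contig rescues the tip
  contigs2 <- contigs; contigs2$has_core_gene[1] <- TRUE
  expect_length(flag_contamination(tr, ann, contigs2), 0)
  # isolates are never flagged
  ann_iso <- ann; ann_iso$source[ann_iso$domain == "virus"] <- "isolate"
  expect_length(flag_contamination(tr, ann_iso, contigs), 0)
  # missing contig metadata: warning, tip retained
  contigs3 <- contigs[-1, ]
  expect_warning(out <- flag_contamination(tr, ann, contigs3),
                 "no contig metadata")
  expect_length(out, 0)
})

test_that("viral tips inside multi-virus clades are never flagged", {
  tr <- parse_newick("((V_1,(V_2,(V_3,(V_4,V_5)))),(B_1,A_1));")
  ann <- toy_annotations(tr$tip.label)
  ann$contig_id <- paste0("ctg_", ann$seq_id)
  contigs <- tibble::tibble(contig_id = paste0("ctg_", tr$tip.label),
                            genome_id = tr$tip.label,
                            has_core_gene = FALSE,
                            has_ncv_besthit_gene = FALSE)
  expect_length(flag_contamination(tr, ann, contigs), 0)
})

test_that("outlier tip filter catches short sequences and long branches", {
  tr <- parse_newick("((s1:0.1,s2:0.1):0.1,(s3:0.1,s4:5.0):0.1);")
  msa <- structure(list(ids = c("s1", "s2", "s3", "s4"),
                        mat = rbind(matrix("A", 3, 300),
                                    c(rep("A", 50), rep("-", 250)))),
                   class = "aars_msa")
  msa$mat <- matrix(msa$mat, nrow = 4)
  rownames(msa$mat) <- msa$ids
  out <- flag_outlier_tips(tr, msa)
  expect_true("s4" %in% out)   # both short (50 aa) and long-branch
})
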