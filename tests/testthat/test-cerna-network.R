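pair_df <- function(m, t) data.frame(mirna_id = m, target_id = t,
                                     stringsAsFactors = FALSE)

test_that("one lncRNA, one miRNA, one mRNA with both links gives one triad", {
  tr <- build_triads("l1", "g1", "m1",
                     pair_df("m1", "l1"), pair_df("m1", "g1"), "W14vW6")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$lncrna_id, "l1")
  expect_equal(tr$mirna_id, "m1")
  expect_equal(tr$mrna_id, "g1")
  expect_equal(tr$group, "W14vW6")
  # missing either link kills the triad
  expect_equal(nrow(build_triads("l1", "g1", "m1",
                                 pair_df("m1", "l1"),
                                 pair_df("m2", "g1"))), 0L)
})

test_that("a gene with 2 miRNAs and 12 lncRNAs in 13 combinations sits in 13 networks", {
  # one miRNA targets 12 lncRNAs, the second targets 1 of them: 13 distinct
  # (lncRNA, miRNA) combinations over a single shared mRNA
  lncs <- sprintf("l%02d", 1:12)
  pl <- rbind(pair_df("mA", lncs), pair_df("mB", "l01"))
  pg <- rbind(pair_df("mA", "ANKRD1_like"), pair_df("mB", "ANKRD1_like"))
  tr <- build_triads(lncs, "ANKRD1_like", c("mA", "mB"), pl, pg)
  expect_equal(nrow(tr), 13L)
  cnt <- per_gene_network_count(tr)
  expect_equal(unname(cnt["ANKRD1_like"]), 13L)
  expect_equal(length(unique(tr$mirna_id)), 2L)
  expect_equal(length(unique(tr$lncrna_id)), 12L)
})

test_that("a gene with one miRNA and 8 lncRNAs sits in 8 networks", {
  lncs <- sprintf("l%d", 1:8)
  tr <- build_triads(lncs, "MYH11_like", "m1",
                     pair_df("m1", lncs), pair_df("m1", "MYH11_like"))
  expect_equal(unname(per_gene_network_count(tr)["MYH11_like"]), 8L)
  expect_equal(nrow(tr), 8L)
})

test_that("triads equal a triple-loop brute-force join on random tables", {
  set.seed(41)
  lncs <- sprintf("L%02d", 1:10)
  genes <- sprintf("G%02d", 1:10)
  mirs <- sprintf("M%02d", 1:10)
  pl <- unique(pair_df(sample(mirs, 40, TRUE), sample(lncs, 40, TRUE)))
  pg <- unique(pair_df(sample(mirs, 40, TRUE), sample(genes, 40, TRUE)))
  de_l <- sample(lncs, 6); de_g <- sample(genes, 6); de_m <- sample(mirs, 6)
  tr <- build_triads(de_l, de_g, de_m, pl, pg)
  brute <- list()
  for (l in de_l) for (m in de_m) for (g in de_g) {
    if (any(pl$mirna_id == m & pl$target_id == l) &&
        any(pg$mirna_id == m & pg$target_id == g))
      brute[[length(brute) + 1L]] <- paste(l, m, g)
  }
  expect_setequal(paste(tr$lncrna_id, tr$mirna_id, tr$mrna_id),
                  unlist(brute))
  expect_equal(anyDuplicated(tr), 0L)
  # deterministic lexicographic order
  expect_equal(order(tr$lncrna_id, tr$mirna_id, tr$mrna_id),
               seq_len(nrow(tr)))
  # per-gene counts against a set-size brute force
  cnt <- per_gene_network_count(tr)
  for (g in names(cnt))
    expect_equal(unname(cnt[g]),
                 nrow(unique(tr[tr$mrna_id == g,
                                c("lncrna_id", "mirna_id")])))
})

test_that("removing one miRNA removes exactly its triads", {
  set.seed(43)
  lncs <- sprintf("L%d", 1:6); genes <- sprintf("G%d", 1:6)
  mirs <- sprintf("M%d", 1:4)
  pl <- unique(pair_df(sample(mirs, 30, TRUE), sample(lncs, 30, TRUE)))
  pg <- unique(pair_df(sample(mirs, 30, TRUE), sample(genes, 30, TRUE)))
  full <- build_triads(lncs, genes, mirs, pl, pg)
  drop <- mirs[1]
  reduced <- build_triads(lncs, genes, setdiff(mirs, drop), pl, pg)
  expect_equal(reduced, full[full$mirna_id != drop, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("the anticorrelation filter keeps only opposed directions", {
  pl <- pair_df("m1", c("l1", "l2"))
  pg <- pair_df("m1", "g1")
  dir <- list(mirna = c(m1 = 2), lncrna = c(l1 = -1.5, l2 = 1.2),
              mrna = c(g1 = -2))
  tr <- build_triads(c("l1", "l2"), "g1", "m1", pl, pg, direction = dir)
  expect_equal(tr$lncrna_id, "l1")   # l2 moves with the miRNA: filtered
})

test_that("planted triads are recovered exactly from planted evidence", {
  b <- tiny_bundle()
  de <- de_table(b$expression)
  mt <- b$truth$mirna_targets
  pl <- mt[mt$target_kind == "lncRNA", c("mirna_id", "target_id")]
  pg <- mt[mt$target_kind == "mRNA", c("mirna_id", "target_id")]
  got <- do.call(rbind, lapply(comparison_groups()$label, function(g) {
    d <- de[de$group == g & de$is_cerna_grade, ]
    build_triads(d$feature_id, d$feature_id, b$truth$de_mirnas[[g]],
                 pl, pg, group = g)
  }))
  # every planted triad is recovered in its planted group
  expect_true(all(paste(b$truth$triads$lncrna_id, b$truth$triads$mirna_id,
                        b$truth$triads$mrna_id, b$truth$triads$group) %in%
                    paste(got$lncrna_id, got$mirna_id, got$mrna_id,
                          got$group)))
  # and with planted-only pair tables no foreign triple appears: a planted
  # profile is shared across every comparison involving its up-stage, so
  # recovery may repeat a triple across those groups, but never invent one
  triple <- function(d) unique(paste(d$lncrna_id, d$mirna_id, d$mrna_id))
  expect_setequal(triple(got), triple(b$truth$triads))
})

test_that("triad edges export one miRNA-lncRNA and one miRNA-mRNA edge each", {
  tr <- build_triads("l1", "g1", "m1", pair_df("m1", "l1"),
                     pair_df("m1", "g1"))
  e <- triads_to_edges(tr)
  expect_setequal(e$edge_type, c("mirna_lncrna", "mirna_mrna"))
  expect_equal(nrow(e), 2L)
  expect_equal(nrow(triads_to_edges(tr[0, ])), 0L)
})
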