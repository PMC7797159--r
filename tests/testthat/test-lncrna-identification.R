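# A hand-built mini transcriptome exercising every cascade branch.
cascade_fixture <- function() {
  tx <- transcript_set(
    transcript_id = c("one_exon", "len200", "len201", "coding_overlap",
                      "ann_lnc", "low_fpkm", "at_floor", "novel_u",
                      "novel_x", "tucp1"),
    gene_id = paste0("g", 1:10),
    chrom = "c1", strand = "+",
    exon_starts = list(1000, c(1000, 1150), c(1000, 1150), c(1000, 2000),
                       c(1000, 2000), c(1000, 2000), c(1000, 2000),
                       c(1000, 2000), c(1000, 2000), c(1000, 2000)),
    exon_ends = list(1500,
                     c(1099, 1249),   # 100 + 100 = 200 nt exactly
                     c(1099, 1250),   # 100 + 101 = 201 nt
                     c(1400, 2400), c(1400, 2400), c(1400, 2400),
                     c(1400, 2400), c(1400, 2400), c(1400, 2400),
                     c(1400, 2400)),
    class_code = c("u", "u", "u", "=", "=", "u", "u", "u", "x", "u"))
  design <- make_design()
  fpkm <- matrix(5, nrow(tx), 12,
                 dimnames = list(tx$transcript_id, design$sample_id))
  fpkm["low_fpkm", ] <- 0.49      # max 0.49 < 0.5 -> removed
  fpkm["at_floor", ] <- 0.1
  fpkm["at_floor", 1] <- 0.5      # max exactly 0.5 -> retained (inclusive)
  expr <- expression_matrix(fpkm, design)
  verdicts <- data.frame(transcript_id = tx$transcript_id,
                         cpc = "noncoding", pfam = "noncoding",
                         phylocsf = "noncoding", cnci = "noncoding",
                         stringsAsFactors = FALSE)
  verdicts[verdicts$transcript_id == "tucp1", "pfam"] <- "coding"
  list(tx = tx, expr = expr, verdicts = verdicts)
}

test_that("each cascade step removes exactly what its rule says", {
  fx <- cascade_fixture()
  res <- filter_cascade(fx$tx, fx$expr, fx$verdicts,
                        annotated_lncrna_ids = "ann_lnc")
  rep <- res$report
  step_of <- function(id) rep$step[rep$transcript_id == id]
  out_of <- function(id) rep$outcome[rep$transcript_id == id]
  expect_equal(step_of("one_exon"), "exon")          # exon number >= 2 fails
  expect_equal(step_of("len200"), "length")          # 200 nt is not > 200
  expect_equal(out_of("len201"), "lncRNA_novel")     # 201 nt survives
  expect_equal(step_of("coding_overlap"), "overlap")
  expect_equal(out_of("ann_lnc"), "lncRNA_annotated")
  expect_equal(step_of("low_fpkm"), "expression")    # max 0.49 < 0.5
  expect_equal(out_of("at_floor"), "lncRNA_novel")   # max 0.5 inclusive
  expect_equal(out_of("novel_u"), "lncRNA_novel")
  expect_equal(out_of("novel_x"), "lncRNA_novel")
  expect_equal(out_of("tucp1"), "TUCP")
})

test_that("the cascade partitions its input", {
  fx <- cascade_fixture()
  res <- filter_cascade(fx$tx, fx$expr, fx$verdicts,
                        annotated_lncrna_ids = "ann_lnc")
  kept <- c(res$lncrna$transcript_id, res$tucp$transcript_id,
            res$annotated$transcript_id)
  removed <- res$report$transcript_id[res$report$outcome == "removed"]
  expect_setequal(c(kept, removed), fx$tx$transcript_id)
  expect_equal(length(kept) + length(removed), nrow(fx$tx))
  expect_equal(anyDuplicated(c(kept, removed)), 0L)
})

test_that("steps 1, 2 and 4 act as order-independent pure predicates", {
  b <- tiny_bundle()
  res <- filter_cascade(b$annotation, b$expression, b$verdicts,
                        b$truth$annotated_lncrna_ids)
  # survivors computed as an unordered conjunction of the predicates
  tx <- b$annotation
  pass_exon <- tx_n_exons(tx) >= 2L
  pass_len <- tx_length(tx) > 200L
  is_ann <- tx$transcript_id %in% b$truth$annotated_lncrna_ids
  pass_overlap <- !(tx$class_code %in% c("=", "c", "j", "e", "o")) | is_ann
  agg <- apply(b$expression$fpkm[tx$transcript_id, , drop = FALSE], 1, max)
  pass_expr <- agg >= 0.5
  survivors <- tx$transcript_id[pass_exon & pass_len & pass_overlap &
                                  (pass_expr | is_ann)]
  kept <- res$report$transcript_id[res$report$outcome != "removed"]
  expect_setequal(kept, survivors)
})

test_that("planted lncRNAs and TUCPs are recovered without misclassification", {
  b <- tiny_bundle()
  res <- filter_cascade(b$annotation, b$expression, b$verdicts,
                        b$truth$annotated_lncrna_ids)
  bt <- b$truth$biotype
  expect_setequal(res$lncrna$transcript_id,
                  names(bt)[bt == "lncRNA_novel"])
  expect_setequal(res$tucp$transcript_id, names(bt)[bt == "TUCP"])
  expect_setequal(res$annotated$transcript_id,
                  names(bt)[bt == "lncRNA_annotated"])
})

test_that("survivors without a verdicts row are reported by name", {
  fx <- cascade_fixture()
  v <- fx$verdicts[fx$verdicts$transcript_id != "novel_u", ]
  expect_error(filter_cascade(fx$tx, fx$expr, v, "ann_lnc"), "novel_u")
})

test_that("lncRNA classes map u to lincRNA and x to antisense", {
  fx <- cascade_fixture()
  res <- filter_cascade(fx$tx, fx$expr, fx$verdicts, "ann_lnc")
  cls <- classify_lncrna(res$lncrna)
  expect_equal(unname(cls[c("novel_u", "novel_x")]),
               c("lincRNA", "antisense"))
  expect_equal(length(classify_lncrna(res$lncrna[0, ])), 0L)
  odd <- transcript_set("t1", "g1", "c1", "+", list(c(1, 500)),
                        list(c(100, 900)), class_code = "i")
  expect_error(classify_lncrna(odd), "t1")
})

test_that("ORF counting handles boundary lengths", {
  expect_equal(count_orfs("CCCCCCGGGTTT"), 0L)               # no ATG
  # ATG + 28 further codons + stop = 29 codons: below the 30-codon floor
  s29 <- paste0("ATG", paste(rep("GGC", 28), collapse = ""), "TAA")
  expect_equal(count_orfs(s29), 0L)
  s30 <- paste0("ATG", paste(rep("GGC", 29), collapse = ""), "TAA")
  expect_equal(count_orfs(s30), 1L)
  # ATG with no downstream stop is not an ORF
  expect_equal(count_orfs(paste0("ATG", paste(rep("GGC", 40), collapse = ""))),
               0L)
})

test_that("ORF counts match a brute-force scan on random sequences", {
  brute_orfs <- function(s, min_codons = 30L) {
    n <- nchar(s); total <- 0L
    for (start in seq_len(max(n - 2L, 0L))) {
      if (substr(s, start, start + 2L) != "ATG") next
      p <- start + 3L
      while (p + 2L <= n) {
        cod <- substr(s, p, p + 2L)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          if ((p - start) / 3L >= min_codons) total <- total + 1L
          break
        }
        p <- p + 3L
      }
    }
    total
  }
  set.seed(21)
  for (i in 1:100) {
    s <- random_dna(sample(90:600, 1))
    expect_equal(count_orfs(s), brute_orfs(s), label = paste("seq", i))
  }
})

test_that("characterization summarizes by biotype and flags missing sequences", {
  b <- tiny_bundle()
  expect_warning(
    ch <- characterize(b$annotation, b$sequences[-1], b$expression),
    "ORF count")
  expect_true(any(is.na(ch$features$n_orfs)))
  ch2 <- characterize(b$annotation, b$sequences, b$expression)
  f <- ch2$features
  expect_setequal(f$transcript_id, b$annotation$transcript_id)
  expect_false(anyNA(f$n_orfs))
  expect_true(all(c("length", "n_exons", "n_orfs", "mean_fpkm") %in%
                    names(ch2$histograms[["mRNA"]])))
  h <- ch2$histograms[["mRNA"]]$length
  expect_equal(sum(h$counts), sum(f$biotype == "mRNA"))
})
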