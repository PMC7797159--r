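test_that("identical configs give identical bundles and identical files", {
  b1 <- generate_dataset(tiny_config(seed = 5L))
  b2 <- generate_dataset(tiny_config(seed = 5L))
  expect_identical(b1, b2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(b1, d1); write_dataset(b2, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # a different seed changes the data
  b3 <- generate_dataset(tiny_config(seed = 6L))
  expect_false(identical(b1$expression$fpkm, b3$expression$fpkm))
})

test_that("generator leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_dataset(tiny_config()))
  expect_identical(.Random.seed, before)
})

test_that("no planted signal means empty DE truth in all six comparisons", {
  cfg <- tiny_config(de_fraction = 0, trans_pair_count = 0L,
                     planted_triads = 0L, cis_pair_distances = integer(),
                     mirna_extra_targets = 0L)
  b <- generate_dataset(cfg)
  expect_equal(length(b$truth$de_features), 6L)
  for (g in names(b$truth$de_features))
    expect_equal(nrow(b$truth$de_features[[g]]), 0L)
})

test_that("planted triads are internally consistent with the target table", {
  b <- tiny_bundle()
  tr <- b$truth$triads
  expect_equal(nrow(tr), 3L)
  mt <- b$truth$mirna_targets
  for (i in seq_len(nrow(tr))) {
    expect_true(any(mt$mirna_id == tr$mirna_id[i] &
                      mt$target_id == tr$lncrna_id[i] &
                      mt$target_kind == "lncRNA"))
    expect_true(any(mt$mirna_id == tr$mirna_id[i] &
                      mt$target_id == tr$mrna_id[i] &
                      mt$target_kind == "mRNA"))
    # triad members are planted DE (ceRNA grade) in the triad's group
    de <- b$truth$de_features[[tr$group[i]]]
    expect_true(all(c(tr$lncrna_id[i], tr$mrna_id[i]) %in% de$feature_id))
    expect_true(tr$mirna_id[i] %in% b$truth$de_mirnas[[tr$group[i]]])
  }
})

test_that("planted seed sites and precursors are really in the sequences", {
  b <- tiny_bundle()
  seqs <- unclass(b$sequences)
  mt <- b$truth$mirna_targets
  for (i in seq_len(nrow(mt))) {
    mature <- b$mirnas$mature_seq[b$mirnas$mirna_id == mt$mirna_id[i]]
    site <- revcomp_chr(substr(mature, 2, 8))
    expect_equal(unname(substr(seqs[mt$target_id[i]], mt$site_pos[i],
                               mt$site_pos[i] + 6L)), unname(site))
  }
  pr <- b$truth$precursors
  for (i in seq_len(nrow(pr))) {
    pre_seq <- b$mirnas$precursor_seq[
      !is.na(b$mirnas$precursor_id) &
        b$mirnas$precursor_id == pr$precursor_id[i]]
    expect_equal(unname(substr(seqs[pr$lncrna_id[i]], pr$start[i],
                               pr$end[i])), unname(pre_seq))
    expect_equal(pr$end[i] - pr$start[i] + 1L, nchar(pre_seq))
  }
})

test_that("with vanishing noise the group-mean log2 ratio equals the planted value", {
  cfg <- tiny_config(fpkm_sigma = 1e-9, trans_noise_sigma = 1e-9)
  b <- generate_dataset(cfg)
  groups <- comparison_groups()
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    truth <- b$truth$de_features[[g$label]]
    if (nrow(truth) == 0) next
    num <- rowMeans(b$expression$fpkm[truth$feature_id,
                                      stage_samples(b$expression, g$numerator),
                                      drop = FALSE])
    den <- rowMeans(b$expression$fpkm[truth$feature_id,
                                      stage_samples(b$expression, g$denominator),
                                      drop = FALSE])
    expect_equal(unname(log2(num / den)), truth$planted_log2fc,
                 tolerance = 1e-3)
  }
})

test_that("planted cis offsets equal the configured span-to-span gaps exactly", {
  b <- tiny_bundle()
  cp <- b$truth$cis_pairs
  spans <- tx_span(b$annotation)
  for (i in seq_len(nrow(cp))) {
    sl <- spans[spans$transcript_id == cp$lncrna_id[i], ]
    sg <- spans[spans$transcript_id == cp$gene_id[i], ]
    expect_equal(sl$chrom, sg$chrom)
    gap <- max(sg$start, sl$start) - min(sg$end, sl$end) - 1L
    expect_equal(max(gap, 0L), cp$distance_bp[i])
  }
  expect_equal(sort(cp$distance_bp),
               sort(tiny_config()$cis_pair_distances))
})

test_that("mRNAs are longer and higher-expressed than lncRNAs, with more exons", {
  b <- default_bundle()
  bt <- b$truth$biotype[b$annotation$transcript_id]
  len <- tx_length(b$annotation)
  nex <- tx_n_exons(b$annotation)
  mfpkm <- rowMeans(b$expression$fpkm)[b$annotation$transcript_id]
  is_m <- bt == "mRNA"; is_l <- bt %in% c("lncRNA_novel", "lncRNA_annotated")
  expect_gt(mean(len[is_m]), mean(len[is_l]))
  expect_gt(mean(nex[is_m]), mean(nex[is_l]))
  expect_gt(mean(mfpkm[is_m]), mean(mfpkm[is_l]))
})

test_that("verdict table marks lncRNAs all-noncoding and TUCPs coding somewhere", {
  b <- tiny_bundle()
  bt <- b$truth$biotype
  v <- b$verdicts
  vm <- as.matrix(v[, c("cpc", "pfam", "phylocsf", "cnci")])
  n_coding <- rowSums(vm == "coding")
  expect_true(all(n_coding[bt[v$transcript_id] == "lncRNA_novel"] == 0))
  expect_true(all(n_coding[bt[v$transcript_id] == "TUCP"] >= 1))
})

test_that("dataset bundles survive a write/read round trip", {
  b <- tiny_bundle()
  d <- withr::local_tempdir()
  write_dataset(b, d)
  b2 <- read_dataset(d)
  expect_equal(b2$expression$fpkm, b$expression$fpkm, tolerance = 1e-6)
  expect_identical(b2$expression$counts, b$expression$counts)
  expect_identical(unclass(b2$sequences), unclass(b$sequences))
  expect_identical(b2$verdicts, b$verdicts)
  expect_equal(b2$truth$cis_pairs, b$truth$cis_pairs)
  expect_equal(b2$truth$triads, b$truth$triads)
  expect_equal(b2$truth$precursors, b$truth$precursors)
  expect_equal(b2$truth$mirna_targets, b$truth$mirna_targets)
  for (g in names(b$truth$de_features))
    expect_equal(b2$truth$de_features[[g]], b$truth$de_features[[g]],
                 tolerance = 1e-6)
  ord <- match(b$annotation$transcript_id, b2$annotation$transcript_id)
  expect_false(anyNA(ord))
  a2 <- b2$annotation[ord, ]
  expect_equal(a2$chrom, b$annotation$chrom)
  expect_equal(unname(a2$exon_starts), unname(b$annotation$exon_starts),
               ignore_attr = TRUE)
  expect_equal(a2$biotype, b$annotation$biotype)
  expect_identical(b2$config, b$config)
})

test_that("infeasible precursor placement is rejected", {
  cfg <- tiny_config()
  # host sequences are extended to fit configured precursors, so force a
  # conflict through a position beyond any plausible host extension
  cfg$planted_precursors$position[1] <- 50L
  b <- generate_dataset(cfg)   # feasible: generator extends the host
  expect_true(nrow(b$truth$precursors) >= 1)
  expect_error(generate_dataset(tiny_config(n_lncrna = 2L)),
               "lncrna_index exceeds|not enough")
})
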