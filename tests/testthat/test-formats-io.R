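test_that("GTF reading groups exon lines into transcripts", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("c1", "src", "exon", "100", "200", ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("c1", "src", "exon", "300", "400", ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t")), f)
  tx <- read_gtf(f)
  expect_equal(nrow(tx), 1L)
  expect_equal(tx$exon_starts[[1]], c(100L, 300L))
  expect_equal(tx$exon_ends[[1]], c(200L, 400L))
  expect_equal(tx$class_code, "=")  # absent attribute means annotated match
})

test_that("empty GTF gives an empty transcript set", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(), f)
  expect_equal(nrow(read_gtf(f)), 0L)
})

test_that("malformed GTF lines are rejected with their line number", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("c1", "src", "exon", "100", "200", ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    "not a gtf line"), f)
  expect_error(read_gtf(f), "line 2")
})

test_that("GTF round trip is lossless on random transcripts", {
  tx <- random_transcripts(50, seed = 11)
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(tx, f)
  tx2 <- read_gtf(f)
  ord <- match(tx$transcript_id, tx2$transcript_id)
  expect_false(anyNA(ord))
  tx2 <- tx2[ord, ]
  for (col in c("transcript_id", "gene_id", "chrom", "strand",
                "class_code", "biotype"))
    expect_equal(tx2[[col]], tx[[col]], ignore_attr = TRUE)
  expect_equal(unname(tx2$exon_starts), unname(tx$exon_starts),
               ignore_attr = TRUE)
  expect_equal(unname(tx2$exon_ends), unname(tx$exon_ends),
               ignore_attr = TRUE)
})

test_that("transcript_set enforces exon invariants", {
  expect_error(transcript_set("t", "g", "c", "+", list(10),
                              list(5)), "start > end")
  expect_error(transcript_set("t", "g", "c", "+", list(integer()),
                              list(integer())), "no exons")
  expect_error(transcript_set(c("t", "t"), c("g", "g"), c("c", "c"),
                              c("+", "+"), list(1, 1), list(5, 5)),
               "duplicate")
  expect_error(transcript_set("t", "g", "c", "+", list(c(1, 5)),
                              list(c(10, 20))), "overlapping")
  # unsorted exon input is sorted on construction
  tx <- transcript_set("t", "g", "c", "+", list(c(300, 100)),
                       list(c(400, 200)))
  expect_equal(tx$exon_starts[[1]], c(100L, 300L))
  expect_equal(tx_length(tx), 202L)
})

test_that("expression tables round-trip through TSV to 6 decimals", {
  b <- tiny_bundle()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(b$expression, f, "fpkm")
  e2 <- read_expression_table(f, b$expression$design)
  expect_equal(e2$fpkm, b$expression$fpkm, tolerance = 1e-6)
  expect_equal(colnames(e2$fpkm), colnames(b$expression$fpkm))
})

test_that("expression table validation catches bad inputs", {
  design <- make_design()
  f <- withr::local_tempfile(fileext = ".tsv")
  # only 11 sample columns against the 12-sample design
  m <- matrix(1, 2, 11,
              dimnames = list(c("a", "b"), design$sample_id[1:11]))
  utils::write.table(data.frame(feature_id = rownames(m), m,
                                check.names = FALSE),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_table(f, design), "missing from table")
  # negative value
  expect_error(expression_matrix(
    matrix(-1, 1, 12, dimnames = list("a", design$sample_id)), design),
    "negative")
  # duplicate feature ids
  m <- matrix(1, 2, 12, dimnames = list(c("a", "a"), design$sample_id))
  utils::write.table(data.frame(feature_id = rownames(m), m,
                                check.names = FALSE),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_table(f, design), "duplicate")
})

test_that("SIF export writes source<TAB>type<TAB>target lines", {
  f <- withr::local_tempfile(fileext = ".sif")
  write_network(network_edges("l1", "g1", "cis"), f, "SIF")
  expect_equal(readLines(f), "l1\tcis\tg1")
  write_network(network_edges(), f, "SIF")
  expect_equal(readLines(f), character())
  expect_error(write_network(network_edges(), f, "DOT"), "unknown")
})

test_that("GraphML round trip preserves the edge multiset", {
  set.seed(5)
  n <- 100
  e <- network_edges(sample(letters, n, TRUE), sample(LETTERS, n, TRUE),
                     sample(c("cis", "trans", "mirna_lncrna", "mirna_mrna"),
                            n, TRUE),
                     round(runif(n), 3))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network(e, f, "GraphML")
  e2 <- read_network(f, "GraphML")
  key <- function(d) sort(paste(d$source, d$target, d$edge_type, d$weight))
  expect_equal(key(e2), key(e))
})

test_that("sequence sets normalize U to T and keep names", {
  s <- sequence_set(c(a = "acgu", b = "UUUU"))
  expect_equal(unclass(s), c(a = "ACGT", b = "TTTT"))
  expect_error(sequence_set(c(a = "")), "empty")
  expect_error(sequence_set(c(a = "ACGZ")), "non-nucleotide")
  expect_error(sequence_set("ACGT"), "named")
})

test_that("FASTA round trip preserves ids and sequences", {
  b <- tiny_bundle()
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(b$sequences, f)
  s2 <- read_fasta(f)
  expect_equal(unclass(s2), unclass(b$sequences))
})
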