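# Shared fixtures: all built in code, nothing on disk.

# A small but fully-featured simulation config for fast module tests.
tiny_config <- function(seed = 42L, ...) {
  args <- list(
    seed = seed,
    n_chrom = 3L, n_mrna = 60L, n_lncrna = 30L, n_tucp = 10L,
    n_annotated_lncrna = 10L, n_filler = 12L, n_mirna = 8L,
    trans_pair_count = 4L,
    cis_pair_distances = c(0L, 1000L, 100000L, 100001L),
    planted_precursors = data.frame(
      precursor_id = c("pre-a", "pre-b", "pre-b"),
      lncrna_index = c(1L, 2L, 3L),
      position = c(309L, 400L, 150L),
      length = c(66L, 61L, 61L)),
    planted_triads = 3L,
    mirna_extra_targets = 4L)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

# Cached default bundle shared across test files (generated once per run).
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(simulation_config(seed = 7L))
    cache
  }
})

tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(tiny_config())
    cache
  }
})

# A 12-sample design matching the staged layout.
make_design <- function(stages = c("W6", "W14", "W22", "W30"), reps = 3L) {
  data.frame(sample_id = paste0(rep(stages, each = reps), "_",
                                rep(seq_len(reps), length(stages))),
             stage = rep(stages, each = reps),
             replicate = rep(seq_len(reps), length(stages)),
             stringsAsFactors = FALSE)
}

# Expression matrix with given per-stage means (features x 4 stages),
# noiseless (each replicate equals the stage mean).
make_expr <- function(stage_means, counts = NULL) {
  design <- make_design()
  m <- stage_means[, design$stage, drop = FALSE]
  colnames(m) <- design$sample_id
  cm <- NULL
  if (!is.null(counts)) {
    cm <- counts[, design$stage, drop = FALSE]
    colnames(cm) <- design$sample_id
  }
  expression_matrix(m, design, counts = cm)
}

# Random transcript set for round-trip and oracle tests.
random_transcripts <- function(n, seed = 1L, chroms = c("c1", "c2", "c3")) {
  set.seed(seed)
  starts <- list(); ends <- list()
  for (i in seq_len(n)) {
    k <- sample(1:5, 1)
    s <- sort(sample(1:500000, k))
    w <- sample(50:300, k, replace = TRUE)
    e <- s + w
    # push apart to guarantee non-overlap
    for (j in seq_len(k)[-1]) {
      if (s[j] <= e[j - 1]) {
        shift <- e[j - 1] - s[j] + 1L + sample(10:100, 1)
        s[j] <- s[j] + shift; e[j] <- e[j] + shift
      }
    }
    starts[[i]] <- s; ends[[i]] <- e
  }
  transcript_set(sprintf("tx%03d", seq_len(n)),
                 sprintf("g%03d", seq_len(n)),
                 sample(chroms, n, replace = TRUE),
                 sample(c("+", "-"), n, replace = TRUE),
                 starts, ends,
                 class_code = sample(c("=", "u", "x", "j", "i"), n,
                                     replace = TRUE),
                 biotype = "unclassified")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
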