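#' Simulation configuration for the synthetic staged-muscle dataset
#'
#' Defines the conditions the generator emulates: a 4-stage (W6/W14/W22/W30),
#' 3-replicate bulk RNA-seq design over a transcriptome containing mRNAs,
#' annotated and novel lncRNAs, TUCPs and transcripts destined for removal by
#' the identification cascade, plus a mature/precursor miRNA complement with
#' planted seed sites, embedded pre-miRNA sequences, cis pairs at exact
#' genomic offsets, latent-factor trans pairs, and ceRNA triads. Every
#' planted signal is recorded in the returned truth object so downstream
#' recovery can be scored.
#'
#' @param seed integer RNG seed; the full bundle is a deterministic function
#'   of the config.
#' @param n_chrom number of background chromosomes.
#' @param n_mrna,n_lncrna,n_tucp,n_annotated_lncrna counts of protein-coding
#'   transcripts, novel lncRNAs, TUCPs and database-annotated lncRNAs.
#' @param n_filler transcripts built to fail the cascade (single-exon, short,
#'   or below the expression floor, in equal thirds).
#' @param n_mirna number of miRNAs (22-nt matures).
#' @param stages stage labels, oldest last.
#' @param n_replicates replicates per stage.
#' @param de_fraction fraction of mRNA+lncRNA features with a planted
#'   stage-dependent expression change.
#' @param de_log2fc_range range the planted |log2 fold change| is drawn from.
#' @param trans_pair_count number of lncRNA-mRNA pairs driven by a shared
#'   stage-level latent factor (their noiseless means are exactly
#'   proportional, Pearson r = 1).
#' @param cis_pair_distances base-pair gaps at which lncRNA-gene cis pairs
#'   are planted, one pair per entry, each on its own chromosome; the gap is
#'   the number of bases strictly between the two spans (0 = adjacent).
#' @param planted_precursors data.frame with columns `precursor_id`,
#'   `lncrna_index` (index into the novel-lncRNA pool), `position` (1-based
#'   start in the host), `length` (nt). The same `precursor_id` may appear
#'   with several hosts; its sequence is generated once and copied verbatim
#'   into each.
#' @param planted_triads number of lncRNA-miRNA-mRNA ceRNA triads to plant
#'   (DE partners plus seed sites), cycled over the comparison groups.
#' @param mirna_extra_targets additional planted seed-site relations (per
#'   target kind) on features without planted DE.
#' @param fpkm_sigma sdlog of the multiplicative lognormal FPKM noise.
#' @param trans_noise_sigma residual sdlog for trans-pair features (their
#'   variance is dominated by the shared regulatory profile).
#' @param nb_dispersion negative-binomial dispersion of the simulated counts.
#' @param lib_depth_m library depth in millions of fragments used to scale
#'   FPKM into expected counts.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chrom = 5L,
                              n_mrna = 1200L,
                              n_lncrna = 300L,
                              n_tucp = 100L,
                              n_annotated_lncrna = 100L,
                              n_filler = 300L,
                              n_mirna = 20L,
                              stages = c("W6", "W14", "W22", "W30"),
                              n_replicates = 3L,
                              de_fraction = 0.1,
                              de_log2fc_range = c(2, 4),
                              trans_pair_count = 20L,
                              cis_pair_distances = c(0L, 500L, 5000L, 50000L,
                                                     100000L, 100001L, 150000L),
                              planted_precursors = data.frame(
                                precursor_id = c("pre-mir-N1", "pre-mir-N2",
                                                 "pre-mir-N2", "pre-mir-N3"),
                                lncrna_index = c(1L, 2L, 3L, 4L),
                                position = c(309L, 1527L, 1101L, 210L),
                                length = c(66L, 61L, 61L, 70L)),
                              planted_triads = 5L,
                              mirna_extra_targets = 10L,
                              fpkm_sigma = 0.1,
                              trans_noise_sigma = 0.05,
                              nb_dispersion = 0.02,
                              lib_depth_m = 30) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_tucp = as.integer(n_tucp),
              n_annotated_lncrna = as.integer(n_annotated_lncrna),
              n_filler = as.integer(n_filler), n_mirna = as.integer(n_mirna),
              stages = as.character(stages),
              n_replicates = as.integer(n_replicates),
              de_fraction = de_fraction,
              de_log2fc_range = as.numeric(de_log2fc_range),
              trans_pair_count = as.integer(trans_pair_count),
              cis_pair_distances = as.integer(cis_pair_distances),
              planted_precursors = planted_precursors,
              planted_triads = as.integer(planted_triads),
              mirna_extra_targets = as.integer(mirna_extra_targets),
              fpkm_sigma = fpkm_sigma,
              trans_noise_sigma = trans_noise_sigma,
              nb_dispersion = nb_dispersion,
              lib_depth_m = lib_depth_m)
  counts <- unlist(cfg[c("n_chrom", "n_mrna", "n_lncrna", "n_tucp",
                         "n_annotated_lncrna", "n_filler", "n_mirna",
                         "n_replicates", "trans_pair_count",
                         "planted_triads", "mirna_extra_targets")])
  if (any(counts < 0)) stop("counts must be >= 0")
  if (de_fraction < 0 || de_fraction >= 1) stop("de_fraction must be in [0,1)")
  if (fpkm_sigma <= 0 || trans_noise_sigma <= 0 || nb_dispersion <= 0)
    stop("fpkm_sigma, trans_noise_sigma and nb_dispersion must be > 0")
  if (nrow(planted_precursors) > 0) {
    need <- c("precursor_id", "lncrna_index", "position", "length")
    if (!all(need %in% names(planted_precursors)))
      stop("planted_precursors needs columns: ", paste(need, collapse = ", "))
    if (any(planted_precursors$lncrna_index > n_lncrna))
      stop("planted_precursors lncrna_index exceeds n_lncrna")
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config: seed", x$seed, "|",
      x$n_mrna, "mRNA,", x$n_lncrna, "lncRNA,", x$n_tucp, "TUCP,",
      x$n_annotated_lncrna, "annotated,", x$n_filler, "filler |",
      length(x$stages), "stages x", x$n_replicates, "replicates\n")
  invisible(x)
}

#' The six ordered stage comparisons
#'
#' Later stage versus earlier stage, matching the staged design's comparison
#' groups (e.g. `W14vW6` compares W14 against W6).
#'
#' @param stages stage labels in temporal order.
#' @return data.frame with columns `label`, `numerator`, `denominator`.
#' @export
comparison_groups <- function(stages = c("W6", "W14", "W22", "W30")) {
  cmb <- utils::combn(stages, 2)
  data.frame(label = paste0(cmb[2, ], "v", cmb[1, ]),
             numerator = cmb[2, ], denominator = cmb[1, ],
             stringsAsFactors = FALSE)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Draw exon structures: returns list(starts, ends) with given total spliced
# length, split over n_exons exons, anchored at genomic position `at`.
make_exons <- function(total_len, n_exons, at) {
  cuts <- sort(sample(seq_len(total_len - 1L),
                      min(n_exons - 1L, total_len - 1L)))
  widths <- diff(c(0L, cuts, total_len))
  introns <- sample(200:2000, length(widths) - 1L, replace = TRUE)
  starts <- integer(length(widths)); ends <- integer(length(widths))
  pos <- at
  for (j in seq_along(widths)) {
    starts[j] <- pos
    ends[j] <- pos + widths[j] - 1L
    if (j < length(widths)) pos <- ends[j] + introns[j] + 1L
  }
  list(starts = starts, ends = ends)
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Produces transcript models, spliced sequences, FPKM/count expression for
#' transcripts and miRNAs, a coding-potential verdicts table, the miRNA set,
#' and a truth object recording everything planted. Identical configs
#' (including seed) give identical bundles; the generator leaves the global
#' RNG state untouched.
#'
#' Directional structure mirrors a real staged muscle transcriptome: mRNAs
#' are longer with more exons than lncRNAs, and lncRNAs have lower mean
#' expression than mRNAs. True lncRNAs are marked noncoding by all four
#' coding-potential predictors, TUCPs coding by at least one.
#'
#' @param config a [simulation_config].
#' @return A list of class `lnc_dataset` with elements `annotation`
#'   ([transcript_set]), `sequences` ([sequence_set]), `expression` and
#'   `mirna_expression` ([expression_matrix]), `mirnas` (data.frame:
#'   `mirna_id`, `mature_seq`, `precursor_id`, `precursor_seq`), `verdicts`
#'   (data.frame), `truth` (list; see Details), `config`.
#'
#' @details The `truth` element contains: `biotype` (named vector),
#'   `annotated_lncrna_ids`, `de_features` (per comparison group a
#'   data.frame `feature_id`, `planted_log2fc`), `de_mirnas` (per group),
#'   `cis_pairs`, `trans_pairs`, `mirna_targets`, `precursors`
#'   (`precursor_id`, `lncrna_id`, `start`, `end`), `triads`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  stages <- config$stages
  groups <- comparison_groups(stages)
  n_samples <- length(stages) * config$n_replicates
  design <- data.frame(
    sample_id = paste0(rep(stages, each = config$n_replicates), "_",
                       rep(seq_len(config$n_replicates), length(stages))),
    stage = rep(stages, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), length(stages)),
    stringsAsFactors = FALSE)

  ## ---- transcript structures ------------------------------------------
  ids <- list(
    mrna = sprintf("MRNA_%04d", seq_len(config$n_mrna)),
    lnc = sprintf("LNC_%06d", seq_len(config$n_lncrna)),
    tucp = sprintf("TUCP_%04d", seq_len(config$n_tucp)),
    ann = sprintf("ALNC_%04d", seq_len(config$n_annotated_lncrna)),
    fill = sprintf("FILL_%04d", seq_len(config$n_filler)))
  all_ids <- unlist(ids, use.names = FALSE)
  n_tx <- length(all_ids)

  kind <- rep(c("mrna", "lnc", "tucp", "ann", "fill"),
              c(config$n_mrna, config$n_lncrna, config$n_tucp,
                config$n_annotated_lncrna, config$n_filler))
  # filler thirds: single-exon / short (<=200 nt) / low expression
  fill_mode <- character(0)
  if (config$n_filler > 0)
    fill_mode <- rep_len(c("one_exon", "short", "low_fpkm"), config$n_filler)

  n_exons <- integer(n_tx); tot_len <- integer(n_tx)
  for (i in seq_len(n_tx)) {
    if (kind[i] == "mrna") {
      n_exons[i] <- sample(6:15, 1L)
      tot_len[i] <- sample(1200:3500, 1L)
    } else if (kind[i] %in% c("lnc", "tucp", "ann")) {
      n_exons[i] <- sample(2:4, 1L)
      tot_len[i] <- sample(300:1500, 1L)
    } else if (fill_mode[i - (n_tx - config$n_filler)] == "one_exon") {
      n_exons[i] <- 1L; tot_len[i] <- sample(300:1500, 1L)
    } else if (fill_mode[i - (n_tx - config$n_filler)] == "short") {
      n_exons[i] <- 2L; tot_len[i] <- sample(100:200, 1L)
    } else {
      n_exons[i] <- sample(2:4, 1L); tot_len[i] <- sample(300:1500, 1L)
    }
  }

  # precursor hosts must be long enough for the planted substring
  pp <- config$planted_precursors
  if (nrow(pp) > 0) {
    for (r in seq_len(nrow(pp))) {
      i <- config$n_mrna + pp$lncrna_index[r]
      need <- pp$position[r] + pp$length[r] - 1L
      if (tot_len[i] < need + 20L) tot_len[i] <- need + 20L
    }
  }

  # genomic placement: one 1-Mb slot per transcript on background
  # chromosomes; planted cis pairs get dedicated chromosomes below
  chroms <- paste0("chr", seq_len(max(config$n_chrom, 1L)))
  chrom_of <- sample(chroms, n_tx, replace = TRUE)
  slot <- integer(n_tx)
  for (ii in split(seq_len(n_tx), chrom_of)) slot[ii] <- seq_along(ii)
  if (any(slot > 2000L))
    stop("too many transcripts per chromosome; increase n_chrom")
  anchor <- (slot - 1L) * 1000000L + 1000L
  strand <- sample(c("+", "-"), n_tx, replace = TRUE, prob = c(0.5, 0.5))

  ex <- vector("list", n_tx)
  for (i in seq_len(n_tx)) ex[[i]] <- make_exons(tot_len[i], n_exons[i], anchor[i])

  # class codes: mRNA and annotated lncRNA match reference exons ("="),
  # novel lncRNA intergenic ("u") or antisense ("x"), TUCP intergenic,
  # filler intergenic
  class_code <- character(n_tx)
  class_code[kind == "mrna"] <- "="
  class_code[kind == "ann"] <- "="
  class_code[kind == "tucp"] <- "u"
  class_code[kind == "fill"] <- "u"
  is_lnc <- kind == "lnc"
  class_code[is_lnc] <- sample(c("u", "x"), sum(is_lnc), replace = TRUE,
                               prob = c(0.797, 0.203))
  biotype <- c(mrna = "mRNA", lnc = "lncRNA_novel", tucp = "TUCP",
               ann = "lncRNA_annotated", fill = "unclassified")[kind]

  ## ---- cis pairs on dedicated chromosomes -----------------------------
  cis_tab <- data.frame(lncrna_id = character(), gene_id = character(),
                        distance_bp = integer(), stringsAsFactors = FALSE)
  n_cis <- length(config$cis_pair_distances)
  if (n_cis > 0) {
    if (config$n_lncrna < nrow(pp) + n_cis || config$n_mrna < n_cis)
      stop("not enough lncRNAs/mRNAs to plant cis pairs")
    lnc_idx <- config$n_mrna + nrow(pp) + seq_len(n_cis)   # skip precursor hosts
    gene_idx <- seq_len(n_cis)
    for (k in seq_len(n_cis)) {
      d <- config$cis_pair_distances[k]
      cc <- paste0("chr_cis", k)
      li <- lnc_idx[k]; gi <- gene_idx[k]
      chrom_of[c(li, gi)] <- cc
      ex[[li]] <- make_exons(tot_len[li], n_exons[li], 1000L)
      lnc_end <- ex[[li]]$ends[length(ex[[li]]$ends)]
      ex[[gi]] <- make_exons(tot_len[gi], n_exons[gi], lnc_end + d + 1L)
      cis_tab[k, ] <- list(all_ids[li], all_ids[gi], d)
    }
  }

  annotation <- transcript_set(all_ids, sub("^[A-Z]+_", "G_", all_ids),
                               chrom_of, strand,
                               lapply(ex, `[[`, "starts"),
                               lapply(ex, `[[`, "ends"),
                               class_code = class_code, biotype = biotype)

  ## ---- expression: stage means with planted DE ------------------------
  base_fpkm <- numeric(n_tx)
  base_fpkm[kind == "mrna"] <- exp(stats::rnorm(config$n_mrna, log(20), 0.8))
  nl <- sum(kind %in% c("lnc", "tucp", "ann"))
  base_fpkm[kind %in% c("lnc", "tucp", "ann")] <-
    pmax(exp(stats::rnorm(nl, log(4), 0.8)), 1)
  if (config$n_filler > 0) {
    fb <- exp(stats::rnorm(config$n_filler, log(10), 0.5))
    fb[fill_mode == "low_fpkm"] <- 0.05
    base_fpkm[kind == "fill"] <- fb
  }

  # stage-mean multipliers, log2 scale; start flat
  stage_l2 <- matrix(0, n_tx, length(stages),
                     dimnames = list(all_ids, stages))

  # reserved features (not eligible for the generic DE draw): trans pairs,
  # triad members get their own structured profiles below
  n_trans <- config$trans_pair_count
  trans_lnc_idx <- integer(0); trans_gene_idx <- integer(0)
  if (n_trans > 0) {
    avail_lnc <- config$n_mrna + setdiff(seq_len(config$n_lncrna),
                                         seq_len(nrow(pp) + n_cis))
    avail_gene <- setdiff(seq_len(config$n_mrna), seq_len(n_cis))
    if (length(avail_lnc) < n_trans || length(avail_gene) < n_trans)
      stop("not enough features to plant trans pairs")
    trans_lnc_idx <- avail_lnc[seq_len(n_trans)]
    trans_gene_idx <- avail_gene[seq_len(n_trans)]
  }
  n_triad <- config$planted_triads
  triad_lnc_idx <- integer(0); triad_gene_idx <- integer(0)
  if (n_triad > 0) {
    avail_lnc <- config$n_mrna + setdiff(seq_len(config$n_lncrna),
                                         c(seq_len(nrow(pp) + n_cis),
                                           trans_lnc_idx - config$n_mrna))
    avail_gene <- setdiff(seq_len(config$n_mrna),
                          c(seq_len(n_cis), trans_gene_idx))
    if (length(avail_lnc) < n_triad || length(avail_gene) < n_triad)
      stop("not enough features to plant triads")
    triad_lnc_idx <- avail_lnc[seq_len(n_triad)]
    triad_gene_idx <- avail_gene[seq_len(n_triad)]
  }
  cis_lnc_idx <- config$n_mrna + nrow(pp) + seq_len(n_cis)
  cis_gene_idx <- seq_len(n_cis)
  reserved <- c(trans_lnc_idx, trans_gene_idx, triad_lnc_idx, triad_gene_idx,
                cis_lnc_idx, cis_gene_idx)

  # generic DE features: a random subset of stages shifted by +/- lfc
  eligible <- setdiff(which(kind %in% c("mrna", "lnc")), reserved)
  n_de <- round(config$de_fraction * length(eligible))
  de_idx <- if (n_de > 0) sample(eligible, n_de) else integer(0)
  for (i in de_idx) {
    k <- sample(seq_len(length(stages) - 1L), 1L)
    up <- sample(seq_along(stages), k)
    lfc <- stats::runif(1, config$de_log2fc_range[1], config$de_log2fc_range[2]) *
      sample(c(-1, 1), 1)
    stage_l2[i, up] <- lfc
  }

  # trans pairs: shared symmetric two-level stage profile (two stages up,
  # two down, 16-fold apart). The balanced split keeps the shared variance
  # large relative to the multiplicative noise, so the linear-scale Pearson
  # correlation stays high, while every between-level stage ratio is a
  # clean 16-fold (well past any DE boundary) and within-level ratios are 1.
  for (k in seq_len(n_trans)) {
    up <- sample(seq_along(stages), 2L)
    prof <- ifelse(seq_along(stages) %in% up, 2, -2)
    stage_l2[trans_lnc_idx[k], ] <- prof
    stage_l2[trans_gene_idx[k], ] <- prof
  }

  # cis pairs: both members DE in a comparison group (cycled over groups)
  # so proximity prediction from the DE lists can see them
  cis_group <- character(0)
  if (n_cis > 0) {
    cis_group <- groups$label[rep_len(seq_len(nrow(groups)), n_cis)]
    for (k in seq_len(n_cis)) {
      g <- groups[groups$label == cis_group[k], ]
      up <- match(g$numerator, stages)
      lfc <- stats::runif(1, max(config$de_log2fc_range[1], 2),
                          config$de_log2fc_range[2])
      stage_l2[cis_lnc_idx[k], up] <- lfc
      stage_l2[cis_gene_idx[k], up] <- lfc
    }
    cis_tab$group <- cis_group
  }

  # triads: lncRNA and mRNA strongly DE in the triad's comparison group
  triad_group <- character(0)
  if (n_triad > 0) {
    triad_group <- groups$label[rep_len(seq_len(nrow(groups)), n_triad)]
    for (k in seq_len(n_triad)) {
      g <- groups[groups$label == triad_group[k], ]
      up <- match(g$numerator, stages)
      lfc <- stats::runif(1, max(config$de_log2fc_range[1], 2),
                          config$de_log2fc_range[2])
      stage_l2[triad_lnc_idx[k], up] <- lfc
      stage_l2[triad_gene_idx[k], up] <- lfc
    }
  }

  stage_mean <- base_fpkm * 2^stage_l2           # features x stages
  mean_by_sample <- stage_mean[, design$stage, drop = FALSE]
  colnames(mean_by_sample) <- design$sample_id

  noise <- matrix(exp(stats::rnorm(n_tx * n_samples, 0, config$fpkm_sigma)),
                  n_tx, n_samples)
  # co-regulated trans pairs carry only residual noise around the shared
  # profile, so their co-expression is dominated by the regulation itself
  tri <- c(trans_lnc_idx, trans_gene_idx)
  if (length(tri) > 0)
    noise[tri, ] <- exp(stats::rnorm(length(tri) * n_samples, 0,
                                     config$trans_noise_sigma))
  fpkm <- mean_by_sample * noise

  len_kb <- tx_length(annotation) / 1000
  count_mu <- mean_by_sample * len_kb * config$lib_depth_m
  counts <- matrix(stats::rnbinom(n_tx * n_samples, mu = count_mu,
                                  size = 1 / config$nb_dispersion),
                   n_tx, n_samples,
                   dimnames = dimnames(mean_by_sample))
  expression <- expression_matrix(fpkm, design, counts = counts)

  # analytic DE truth per group from planted stage means
  de_features <- stats::setNames(vector("list", nrow(groups)), groups$label)
  for (gi in seq_len(nrow(groups))) {
    l2 <- stage_l2[, match(groups$numerator[gi], stages)] -
      stage_l2[, match(groups$denominator[gi], stages)]
    sel <- which(abs(l2) > 0 & kind %in% c("mrna", "lnc"))
    de_features[[gi]] <- data.frame(feature_id = all_ids[sel],
                                    planted_log2fc = unname(l2[sel]),
                                    stringsAsFactors = FALSE)
  }

  ## ---- sequences, miRNAs, seed sites, precursors ----------------------
  seqs <- vapply(tot_len, random_seq, "")
  names(seqs) <- all_ids

  mirna_ids <- sprintf("mir-%03d", seq_len(config$n_mirna))
  matures <- vapply(rep(22L, config$n_mirna), random_seq, "")

  # pre-miRNA sequences copied verbatim into hosts
  prec_tab <- data.frame(precursor_id = character(), lncrna_id = character(),
                         start = integer(), end = integer(),
                         stringsAsFactors = FALSE)
  prec_seqs <- character(0)
  if (nrow(pp) > 0) {
    for (pid in unique(pp$precursor_id)) {
      len <- pp$length[pp$precursor_id == pid][1]
      prec_seqs[pid] <- random_seq(len)
    }
    for (r in seq_len(nrow(pp))) {
      host <- all_ids[config$n_mrna + pp$lncrna_index[r]]
      s <- pp$position[r]; e <- s + pp$length[r] - 1L
      if (e > nchar(seqs[host]))
        stop("precursor ", pp$precursor_id[r], " does not fit in host ", host)
      substr(seqs[host], s, e) <- prec_seqs[pp$precursor_id[r]]
      prec_tab[nrow(prec_tab) + 1L, ] <- list(pp$precursor_id[r], host, s, e)
    }
  }

  # seed sites: triad miRNAs target their lncRNA and mRNA; extra targets on
  # features with no planted DE. Sites are placed away from precursor spans.
  occupied <- lapply(stats::setNames(vector("list", n_tx), all_ids),
                     function(x) integer(0))
  for (r in seq_len(nrow(prec_tab)))
    occupied[[prec_tab$lncrna_id[r]]] <-
      c(occupied[[prec_tab$lncrna_id[r]]], prec_tab$start[r]:prec_tab$end[r])
  plant_site <- function(target_id, mature) {
    site <- revcomp(substr(mature, 2L, 8L))
    L <- nchar(seqs[target_id])
    free <- setdiff(seq_len(L - 6L), unique(unlist(
      lapply(occupied[[target_id]], function(p) (p - 6L):p))))
    free <- free[free >= 1L]
    if (length(free) == 0L) stop("no room for seed site in ", target_id)
    pos <- if (length(free) == 1L) free else sample(free, 1L)
    substr(seqs[target_id], pos, pos + 6L) <<- site
    occupied[[target_id]] <<- c(occupied[[target_id]], pos:(pos + 6L))
    pos
  }

  mt <- data.frame(mirna_id = character(), target_id = character(),
                   target_kind = character(), site_pos = integer(),
                   stringsAsFactors = FALSE)
  triad_mirna <- character(0)
  if (n_triad > 0) {
    if (config$n_mirna < n_triad) stop("not enough miRNAs for planted triads")
    triad_mirna <- mirna_ids[seq_len(n_triad)]
    for (k in seq_len(n_triad)) {
      l_id <- all_ids[triad_lnc_idx[k]]; g_id <- all_ids[triad_gene_idx[k]]
      mt[nrow(mt) + 1L, ] <- list(triad_mirna[k], l_id, "lncRNA",
                                  plant_site(l_id, matures[k]))
      mt[nrow(mt) + 1L, ] <- list(triad_mirna[k], g_id, "mRNA",
                                  plant_site(g_id, matures[k]))
    }
  }
  if (config$mirna_extra_targets > 0 && config$n_mirna > n_triad) {
    flat_lnc <- all_ids[config$n_mrna + which(rowSums(abs(
      stage_l2[config$n_mrna + seq_len(config$n_lncrna), , drop = FALSE])) == 0)]
    flat_gene <- all_ids[which(rowSums(abs(
      stage_l2[seq_len(config$n_mrna), , drop = FALSE])) == 0)]
    other_mirna <- mirna_ids[(n_triad + 1L):config$n_mirna]
    n_extra <- min(config$mirna_extra_targets,
                   length(flat_lnc), length(flat_gene))
    for (k in seq_len(n_extra)) {
      m <- other_mirna[1L + (k - 1L) %% length(other_mirna)]
      mi <- match(m, mirna_ids)
      mt[nrow(mt) + 1L, ] <- list(m, flat_lnc[k], "lncRNA",
                                  plant_site(flat_lnc[k], matures[mi]))
      mt[nrow(mt) + 1L, ] <- list(m, flat_gene[k], "mRNA",
                                  plant_site(flat_gene[k], matures[mi]))
    }
  }

  mirnas <- data.frame(mirna_id = mirna_ids, mature_seq = matures,
                       precursor_id = NA_character_,
                       precursor_seq = NA_character_,
                       stringsAsFactors = FALSE)
  if (length(prec_seqs) > 0) {
    host_mirna <- mirna_ids[config$n_mirna - seq_along(prec_seqs) + 1L]
    mirnas$precursor_id[match(host_mirna, mirnas$mirna_id)] <- names(prec_seqs)
    mirnas$precursor_seq[match(host_mirna, mirnas$mirna_id)] <- unname(prec_seqs)
  }

  ## ---- miRNA expression ----------------------------------------------
  mir_base <- exp(stats::rnorm(config$n_mirna, log(50), 0.6))
  mir_l2 <- matrix(0, config$n_mirna, length(stages),
                   dimnames = list(mirna_ids, stages))
  de_mirnas <- stats::setNames(vector("list", nrow(groups)), groups$label)
  for (gi in seq_len(nrow(groups))) de_mirnas[[gi]] <- character(0)
  if (n_triad > 0) {
    for (k in seq_len(n_triad)) {
      g <- groups[groups$label == triad_group[k], ]
      mir_l2[k, match(g$numerator, stages)] <- 2.5
    }
  }
  for (gi in seq_len(nrow(groups))) {
    l2 <- mir_l2[, match(groups$numerator[gi], stages)] -
      mir_l2[, match(groups$denominator[gi], stages)]
    de_mirnas[[gi]] <- mirna_ids[abs(l2) > 0]
  }
  mir_stage_mean <- mir_base * 2^mir_l2
  mir_mu <- mir_stage_mean[, design$stage, drop = FALSE]
  colnames(mir_mu) <- design$sample_id
  mir_fpkm <- mir_mu * matrix(exp(stats::rnorm(config$n_mirna * n_samples, 0,
                                               config$fpkm_sigma)),
                              config$n_mirna, n_samples)
  mir_counts <- matrix(stats::rnbinom(config$n_mirna * n_samples,
                                      mu = mir_mu * 10,
                                      size = 1 / config$nb_dispersion),
                       config$n_mirna, n_samples, dimnames = dimnames(mir_mu))
  mirna_expression <- expression_matrix(mir_fpkm, design, counts = mir_counts)

  ## ---- verdicts --------------------------------------------------------
  verdict_cols <- c("cpc", "pfam", "phylocsf", "cnci")
  verdicts <- data.frame(transcript_id = all_ids, stringsAsFactors = FALSE)
  for (cc in verdict_cols) verdicts[[cc]] <- "noncoding"
  verdicts[kind == "mrna", verdict_cols] <- "coding"
  if (config$n_tucp > 0) {
    for (i in which(kind == "tucp")) {
      n_coding <- sample(1:4, 1L)
      verdicts[i, sample(verdict_cols, n_coding)] <- "coding"
    }
  }

  truth <- list(
    biotype = stats::setNames(biotype, all_ids),
    annotated_lncrna_ids = ids$ann,
    de_features = de_features,
    de_mirnas = de_mirnas,
    cis_pairs = cis_tab,
    trans_pairs = data.frame(lncrna_id = all_ids[trans_lnc_idx],
                             gene_id = all_ids[trans_gene_idx],
                             stringsAsFactors = FALSE),
    mirna_targets = mt,
    precursors = prec_tab,
    triads = data.frame(lncrna_id = all_ids[triad_lnc_idx],
                        mirna_id = triad_mirna,
                        mrna_id = all_ids[triad_gene_idx],
                        group = triad_group,
                        stringsAsFactors = FALSE))

  structure(list(annotation = annotation,
                 sequences = sequence_set(seqs),
                 expression = expression,
                 mirna_expression = mirna_expression,
                 mirnas = mirnas,
                 verdicts = verdicts,
                 truth = truth,
                 config = config),
            class = "lnc_dataset")
}

#' @export
print.lnc_dataset <- function(x, ...) {
  cat("lnc_dataset:", nrow(x$annotation), "transcripts,",
      nrow(x$mirnas), "miRNAs,",
      ncol(x$expression$fpkm), "samples (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a synthetic dataset bundle to a directory
#'
#' Writes the exact external formats the pipeline consumes: GTF annotation,
#' transcript FASTA, miRNA FASTA (precursor records suffixed `-pre`),
#' FPKM/count TSVs for transcripts and miRNAs, the design and verdicts
#' tables, the simulation config as YAML, and the truth tables under
#' `truth/`.
#'
#' @param bundle an `lnc_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "lnc_dataset"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  write_gtf(bundle$annotation, file.path(dir, "annotation.gtf"))
  write_fasta(bundle$sequences, file.path(dir, "transcripts.fa"))
  m <- bundle$mirnas
  fa <- stats::setNames(m$mature_seq, m$mirna_id)
  has_pre <- !is.na(m$precursor_id) & !duplicated(m$precursor_id)
  if (any(has_pre))
    fa <- c(fa, stats::setNames(m$precursor_seq[has_pre],
                                paste0(m$mirna_id[has_pre], "-pre")))
  write_fasta(sequence_set(fa), file.path(dir, "mirnas.fa"))
  write_tsv(m, file.path(dir, "mirnas.tsv"))
  write_expression_table(bundle$expression, file.path(dir, "fpkm.tsv"), "fpkm")
  write_expression_table(bundle$expression, file.path(dir, "counts.tsv"), "counts")
  write_expression_table(bundle$mirna_expression,
                         file.path(dir, "mirna_fpkm.tsv"), "fpkm")
  write_expression_table(bundle$mirna_expression,
                         file.path(dir, "mirna_counts.tsv"), "counts")
  write_tsv(bundle$expression$design, file.path(dir, "design.tsv"))
  write_tsv(bundle$verdicts, file.path(dir, "verdicts.tsv"))

  td <- file.path(dir, "truth")
  dir.create(td, showWarnings = FALSE)
  tr <- bundle$truth
  write_tsv(data.frame(transcript_id = names(tr$biotype),
                       biotype = unname(tr$biotype)),
            file.path(td, "biotype.tsv"))
  writeLines(tr$annotated_lncrna_ids, file.path(td, "annotated_lncrna_ids.txt"))
  de <- do.call(rbind, lapply(names(tr$de_features), function(g) {
    d <- tr$de_features[[g]]
    if (nrow(d) == 0) return(NULL)
    cbind(group = g, d)
  }))
  if (is.null(de))
    de <- data.frame(group = character(), feature_id = character(),
                     planted_log2fc = numeric())
  write_tsv(de, file.path(td, "de_features.tsv"))
  dm <- do.call(rbind, lapply(names(tr$de_mirnas), function(g)
    if (length(tr$de_mirnas[[g]]) > 0)
      data.frame(group = g, mirna_id = tr$de_mirnas[[g]])))
  if (is.null(dm)) dm <- data.frame(group = character(), mirna_id = character())
  write_tsv(dm, file.path(td, "de_mirnas.tsv"))
  write_tsv(tr$cis_pairs, file.path(td, "cis_pairs.tsv"))
  write_tsv(tr$trans_pairs, file.path(td, "trans_pairs.tsv"))
  write_tsv(tr$mirna_targets, file.path(td, "mirna_targets.tsv"))
  write_tsv(tr$precursors, file.path(td, "precursors.tsv"))
  write_tsv(tr$triads, file.path(td, "triads.tsv"))
  write_config(bundle$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read back a dataset bundle written by [write_dataset()]
#'
#' @param dir the bundle directory.
#' @return An `lnc_dataset`.
#' @export
read_dataset <- function(dir) {
  config <- read_config(file.path(dir, "config.yaml"))
  design <- read_tsv(file.path(dir, "design.tsv"))
  expression <- read_expression_table(file.path(dir, "fpkm.tsv"), design,
                                      counts_path = file.path(dir, "counts.tsv"))
  mirna_expression <- read_expression_table(
    file.path(dir, "mirna_fpkm.tsv"), design,
    counts_path = file.path(dir, "mirna_counts.tsv"))
  td <- file.path(dir, "truth")
  de <- read_tsv(file.path(td, "de_features.tsv"))
  dm <- read_tsv(file.path(td, "de_mirnas.tsv"))
  groups <- comparison_groups(config$stages)$label
  de_features <- stats::setNames(lapply(groups, function(g) {
    d <- de[de$group == g, c("feature_id", "planted_log2fc"), drop = FALSE]
    rownames(d) <- NULL
    d
  }), groups)
  de_mirnas <- stats::setNames(lapply(groups, function(g)
    dm$mirna_id[dm$group == g]), groups)
  bt <- read_tsv(file.path(td, "biotype.tsv"))
  truth <- list(
    biotype = stats::setNames(bt$biotype, bt$transcript_id),
    annotated_lncrna_ids = readLines(file.path(td, "annotated_lncrna_ids.txt")),
    de_features = de_features,
    de_mirnas = de_mirnas,
    cis_pairs = read_tsv(file.path(td, "cis_pairs.tsv")),
    trans_pairs = read_tsv(file.path(td, "trans_pairs.tsv")),
    mirna_targets = read_tsv(file.path(td, "mirna_targets.tsv")),
    precursors = read_tsv(file.path(td, "precursors.tsv")),
    triads = read_tsv(file.path(td, "triads.tsv")))
  mirnas <- read_tsv(file.path(dir, "mirnas.tsv"))
  mirnas$precursor_id <- as.character(mirnas$precursor_id)
  mirnas$precursor_seq <- as.character(mirnas$precursor_seq)
  structure(list(annotation = read_gtf(file.path(dir, "annotation.gtf")),
                 sequences = read_fasta(file.path(dir, "transcripts.fa")),
                 expression = expression,
                 mirna_expression = mirna_expression,
                 mirnas = mirnas,
                 verdicts = read_verdicts(file.path(dir, "verdicts.tsv")),
                 truth = truth,
                 config = config),
            class = "lnc_dataset")
}

#' Write / read a simulation config as YAML
#'
#' The YAML mirrors [simulation_config()] field for field.
#'
#' @param config a `simulation_config`.
#' @param path YAML file path.
#' @return [write_config()] returns `path` invisibly; [read_config()] a
#'   `simulation_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$planted_precursors <- as.list(x$planted_precursors)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$planted_precursors <- as.data.frame(x$planted_precursors,
                                        stringsAsFactors = FALSE)
  if (nrow(x$planted_precursors) == 0)
    x$planted_precursors <- data.frame(precursor_id = character(),
                                       lncrna_index = integer(),
                                       position = integer(), length = integer())
  do.call(simulation_config, x)
}
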