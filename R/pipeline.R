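#' Pipeline configuration
#'
#' Bundles every numeric threshold, toggle and path the pipeline uses. All
#' defaults follow the analysis rules the pipeline implements: fold change
#' >= 1.7 and q < 0.05 for DE lists, |log2FC| >= 1 for ceRNA-grade calls,
#' FPKM >= 0.5 expression floor, 100-kb cis window, Pearson r > 0.95 for
#' trans targets, STRING combined score > 700, enrichment q < 0.05.
#'
#' @param input_dir directory holding the inputs (layout of
#'   [write_dataset()]: `annotation.gtf`, `transcripts.fa`, `fpkm.tsv`,
#'   `counts.tsv`, `design.tsv`, `verdicts.tsv`, `mirnas.fa`/`mirnas.tsv`,
#'   optionally `gene_sets.tsv`, `string_edges.tsv`,
#'   `truth/annotated_lncrna_ids.txt`).
#' @param output_dir directory the stage outputs are written to.
#' @param fc linear fold-change threshold for DE calls.
#' @param cerna_log2fc `|log2FC|` threshold for ceRNA-grade calls.
#' @param q FDR threshold for DE and DEM calls.
#' @param fpkm_min expression floor for the identification cascade and the
#'   enrichment universe.
#' @param fpkm_aggregate FPKM aggregate across samples (`"max"`/`"mean"`).
#' @param cis_window_bp cis window in bp.
#' @param trans_r trans correlation threshold.
#' @param trans_abs use `|r|` for trans targets.
#' @param ppi_score strict lower bound on STRING combined score.
#' @param enrich_q enrichment significance threshold.
#' @param ease EASE-style k-1 correction in enrichment.
#' @param seed seed used by the `simulate` stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = ".", output_dir = "lncnet_out",
                            fc = 1.7, cerna_log2fc = 1.0, q = 0.05,
                            fpkm_min = 0.5, fpkm_aggregate = "max",
                            cis_window_bp = 100000L, trans_r = 0.95,
                            trans_abs = FALSE, ppi_score = 700L,
                            enrich_q = 0.05, ease = FALSE, seed = 1L) {
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              fc = fc, cerna_log2fc = cerna_log2fc, q = q,
              fpkm_min = fpkm_min, fpkm_aggregate = fpkm_aggregate,
              cis_window_bp = as.integer(cis_window_bp),
              trans_r = trans_r, trans_abs = isTRUE(trans_abs),
              ppi_score = as.integer(ppi_score), enrich_q = enrich_q,
              ease = isTRUE(ease), seed = as.integer(seed))
  num <- unlist(cfg[c("fc", "cerna_log2fc", "q", "fpkm_min",
                      "cis_window_bp", "trans_r", "ppi_score", "enrich_q")])
  if (any(num <= 0)) stop("thresholds must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline config as YAML
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @return [write_pipeline_config()] returns `path` invisibly;
#'   [read_pipeline_config()] a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_stage <- function(stage, ...) {
  message(sprintf("[lncnet:%s] %s", stage, paste0(...)))
}

stage_input <- function(stage, path) {
  if (!file.exists(path))
    stop("stage '", stage, "' missing input file: ", path)
  path
}

#' Run the integrative lncRNA pipeline end to end
#'
#' Executes, in order: `identify` (five-step cascade + classification +
#' characterization), `diffexp` (six stage comparisons for transcripts and
#' miRNAs), `targets` (cis by proximity, trans by correlation, per group),
#' `mirna` (seed-match target prediction and precursor homology), `cerna`
#' (triad assembly per group), `enrich` (hypergeometric, if
#' `gene_sets.tsv` is present among the inputs — otherwise skipped unless
#' explicitly requested), `ppi` (STRING score filter, same rule for
#' `string_edges.tsv`), and `export` (SIF + GraphML). Every intermediate is
#' written as TSV under `output_dir`; `report.json` records input/output
#' counts, the parameter echo, package version and seed. Outputs are a
#' deterministic function of inputs and config; stage timing goes to the
#' message log only, so reruns are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages to run (default: all
#'   applicable).
#' @return The run report, invisibly (a list mirroring `report.json`).
#' @export
run_pipeline <- function(config,
                         stages = c("identify", "diffexp", "targets",
                                    "mirna", "cerna", "enrich", "ppi",
                                    "export")) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("identify", "diffexp", "targets", "mirna", "cerna",
                  "enrich", "ppi", "export")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  ind <- config$input_dir; outd <- config$output_dir
  if (!dir.exists(outd)) dir.create(outd, recursive = TRUE)
  t0 <- Sys.time()
  report <- list(package = "lncnet",
                 version = as.character(utils::packageVersion("lncnet")),
                 seed = config$seed,
                 parameters = unclass(config),
                 stages = list())
  groups <- NULL

  ## ---- shared inputs ---------------------------------------------------
  annotation <- read_gtf(stage_input("identify",
                                     file.path(ind, "annotation.gtf")))
  design <- read_tsv(stage_input("identify", file.path(ind, "design.tsv")))
  expr <- read_expression_table(
    stage_input("identify", file.path(ind, "fpkm.tsv")), design,
    counts_path = if (file.exists(file.path(ind, "counts.tsv")))
      file.path(ind, "counts.tsv"))
  sequences <- read_fasta(stage_input("identify",
                                      file.path(ind, "transcripts.fa")))
  groups <- comparison_groups(unique(design$stage))
  # reference coding transcripts: exonic overlap with annotation, not lncRNA
  ann_ids_file <- file.path(ind, "truth", "annotated_lncrna_ids.txt")
  annotated_ids <- if (file.exists(ann_ids_file)) readLines(ann_ids_file)
                   else character()
  mrna_ids <- annotation$transcript_id[
    annotation$class_code %in% OVERLAP_CLASS_CODES &
      !annotation$transcript_id %in% annotated_ids]

  lnc_ids <- character(); cerna_sets <- NULL
  de <- NULL; de_mir <- NULL
  pairs_lnc <- NULL; pairs_mrna <- NULL
  targets_tab <- NULL; triads <- NULL

  ## ---- identify --------------------------------------------------------
  if ("identify" %in% stages) {
    verdicts <- read_verdicts(stage_input("identify",
                                          file.path(ind, "verdicts.tsv")))
    res <- filter_cascade(annotation, expr, verdicts,
                          annotated_lncrna_ids = annotated_ids,
                          fpkm_min = config$fpkm_min,
                          fpkm_aggregate = config$fpkm_aggregate)
    classes <- classify_lncrna(res$lncrna)
    lnc_all <- rbind(res$lncrna, res$annotated)
    lnc_all$biotype <- rep(c("lncRNA_novel", "lncRNA_annotated"),
                           c(nrow(res$lncrna), nrow(res$annotated)))
    chr_tx <- annotation
    chr_tx$biotype <- ifelse(
      chr_tx$transcript_id %in% res$lncrna$transcript_id, "lncRNA_novel",
      ifelse(chr_tx$transcript_id %in% res$annotated$transcript_id,
             "lncRNA_annotated",
             ifelse(chr_tx$transcript_id %in% res$tucp$transcript_id, "TUCP",
                    ifelse(chr_tx$transcript_id %in% mrna_ids, "mRNA",
                           "unclassified"))))
    char <- characterize(chr_tx, sequences, expr)
    write_tsv(res$report, file.path(outd, "filter_report.tsv"))
    write_tsv(data.frame(transcript_id = names(classes),
                         class = unname(classes)),
              file.path(outd, "lncrna_classes.tsv"))
    write_tsv(char$features, file.path(outd, "characterization.tsv"))
    lnc_ids <- lnc_all$transcript_id
    report$stages$identify <- list(
      n_input = nrow(annotation), n_lncrna_novel = nrow(res$lncrna),
      n_lncrna_annotated = nrow(res$annotated), n_tucp = nrow(res$tucp),
      n_lincRNA = sum(classes == "lincRNA"),
      n_antisense = sum(classes == "antisense"))
    log_stage("identify", nrow(res$lncrna), " novel lncRNA, ",
              nrow(res$tucp), " TUCP from ", nrow(annotation), " transcripts")
  }

  ## ---- diffexp ---------------------------------------------------------
  if (any(c("diffexp", "targets", "cerna", "enrich", "ppi") %in% stages)) {
    if (is.null(expr$counts))
      stop("stage 'diffexp' missing input file: ", file.path(ind, "counts.tsv"))
    de <- de_table(expr, groups, fc_threshold = config$fc,
                   cerna_log2fc = config$cerna_log2fc,
                   q_threshold = config$q)
    write_tsv(de, file.path(outd, "de_results.tsv"))
    de_sets <- lapply(split(de, de$group),
                      function(d) d$feature_id[d$is_de])
    venn <- venn_membership(
      lapply(de_sets, function(s) intersect(s, lnc_ids))[groups$label],
      groups)
    write_tsv(venn$regions, file.path(outd, "venn_regions.tsv"))
    mir_path <- file.path(ind, "mirna_fpkm.tsv")
    de_mir <- NULL
    if (file.exists(mir_path)) {
      mir_expr <- read_expression_table(
        mir_path, design,
        counts_path = stage_input("diffexp",
                                  file.path(ind, "mirna_counts.tsv")))
      de_mir <- do.call(rbind, lapply(seq_len(nrow(groups)), function(gi) {
        g <- groups[gi, ]
        tst <- nb_test(mir_expr, g)
        data.frame(mirna_id = tst$feature_id, group = g$label,
                   p = tst$p, q = bh_adjust(tst$p),
                   stringsAsFactors = FALSE)
      }))
      de_mir$is_dem <- de_mir$q < config$q
      write_tsv(de_mir, file.path(outd, "de_mirnas.tsv"))
    }
    n_de_lnc <- vapply(groups$label, function(g)
      length(intersect(de_sets[[g]], lnc_ids)), integer(1))
    report$stages$diffexp <- list(
      n_features = nrow(expr$fpkm), n_groups = nrow(groups),
      n_de_per_group = as.list(stats::setNames(
        vapply(de_sets[groups$label], length, integer(1)), groups$label)),
      n_de_lncrna_per_group = as.list(n_de_lnc),
      n_dem = if (!is.null(de_mir)) sum(de_mir$is_dem) else 0L)
    log_stage("diffexp", "DE features per group: ",
              paste(vapply(de_sets[groups$label], length, integer(1)),
                    collapse = "/"))
  }

  ## ---- targets ---------------------------------------------------------
  if (any(c("targets", "cerna", "enrich", "ppi") %in% stages)) {
    per_group <- lapply(seq_len(nrow(groups)), function(gi) {
      g <- groups$label[gi]
      d <- de[de$group == g & de$is_de, ]
      lnc <- intersect(d$feature_id, lnc_ids)
      deg <- intersect(d$feature_id, mrna_ids)
      cis <- cis_targets(annotation[annotation$transcript_id %in% lnc, ],
                         annotation[annotation$transcript_id %in% deg, ],
                         window_bp = config$cis_window_bp)
      trn <- trans_targets(expr, lnc, deg, r_threshold = config$trans_r,
                           use_abs = config$trans_abs)
      out <- rbind(
        if (nrow(cis) > 0) data.frame(cis, r = NA_real_, group = g),
        if (nrow(trn) > 0) data.frame(trn[, c("lncrna_id", "gene_id", "mode")],
                                      distance_bp = NA_integer_,
                                      r = trn$r, group = g)[,
          c("lncrna_id", "gene_id", "mode", "distance_bp", "r", "group")])
      out
    })
    targets_tab <- do.call(rbind, per_group)
    if (is.null(targets_tab))
      targets_tab <- data.frame(lncrna_id = character(), gene_id = character(),
                                mode = character(), distance_bp = integer(),
                                r = numeric(), group = character())
    write_tsv(targets_tab, file.path(outd, "target_pairs.tsv"))
    report$stages$targets <- list(n_cis = sum(targets_tab$mode == "cis"),
                                  n_trans = sum(targets_tab$mode == "trans"))
    log_stage("targets", sum(targets_tab$mode == "cis"), " cis, ",
              sum(targets_tab$mode == "trans"), " trans pairs")
  }

  ## ---- mirna -----------------------------------------------------------
  if (any(c("mirna", "cerna") %in% stages)) {
    mir_fa <- file.path(ind, "mirnas.fa")
    mirnas <- read_mirna_fasta(stage_input(
      if ("mirna" %in% stages) "mirna" else "cerna", mir_fa))
    lnc_seqs <- sequences[intersect(lnc_ids, names(sequences))]
    mrna_seqs <- sequences[intersect(mrna_ids, names(sequences))]
    pairs_lnc <- predict_targets(mirnas, lnc_seqs, "lncRNA")
    pairs_mrna <- predict_targets(mirnas, mrna_seqs, "mRNA")
    homology <- precursor_homology(lnc_seqs, mirnas)
    write_tsv(rbind(pairs_lnc, pairs_mrna),
              file.path(outd, "mirna_targets.tsv"))
    write_tsv(homology, file.path(outd, "precursor_homology.tsv"))
    report$stages$mirna <- list(n_lncrna_pairs = nrow(pairs_lnc),
                                n_mrna_pairs = nrow(pairs_mrna),
                                n_homology_hits = nrow(homology))
    log_stage("mirna", nrow(pairs_lnc), "+", nrow(pairs_mrna),
              " target pairs, ", nrow(homology), " precursor hits")
  }

  ## ---- cerna -----------------------------------------------------------
  if ("cerna" %in% stages) {
    if (is.null(de_mir))
      stop("stage 'cerna' missing input file: ",
           file.path(ind, "mirna_fpkm.tsv"))
    triads <- do.call(rbind, lapply(groups$label, function(g) {
      d <- de[de$group == g & de$is_cerna_grade, ]
      dm <- de_mir$mirna_id[de_mir$group == g & de_mir$is_dem]
      build_triads(intersect(d$feature_id, lnc_ids),
                   intersect(d$feature_id, mrna_ids),
                   dm,
                   pairs_lnc[, c("mirna_id", "target_id")],
                   pairs_mrna[, c("mirna_id", "target_id")],
                   group = g)
    }))
    write_tsv(triads, file.path(outd, "cerna_triads.tsv"))
    counts <- per_gene_network_count(triads)
    write_tsv(data.frame(mrna_id = names(counts), n_networks = counts),
              file.path(outd, "cerna_gene_counts.tsv"))
    report$stages$cerna <- list(n_triads = nrow(triads),
                                n_genes = length(counts))
    log_stage("cerna", nrow(triads), " triads across ",
              length(counts), " genes")
  }

  ## ---- enrich ----------------------------------------------------------
  # enrich and ppi need optional side inputs: skipped silently in a default
  # all-stage run when the file is absent, an error when requested by name
  explicit <- !missing(stages)
  gs_path <- file.path(ind, "gene_sets.tsv")
  if ("enrich" %in% stages && explicit && !file.exists(gs_path))
    stage_input("enrich", gs_path)
  if ("enrich" %in% stages && file.exists(gs_path)) {
    terms <- read_gene_sets(gs_path)
    universe <- rownames(expr$fpkm)[apply(expr$fpkm, 1L, max) >= config$fpkm_min]
    universe <- intersect(universe, mrna_ids)
    enr <- do.call(rbind, lapply(groups$label, function(g) {
      tg <- targets_tab$gene_id[targets_tab$group == g]
      q <- intersect(unique(tg), universe)
      if (length(q) == 0L) return(NULL)
      e <- enrich(q, universe, terms, q_threshold = config$enrich_q,
                  ease = config$ease)
      if (nrow(e) == 0L) return(NULL)
      cbind(group = g, e)
    }))
    if (is.null(enr)) enr <- data.frame(group = character())
    write_tsv(enr, file.path(outd, "enrichment.tsv"))
    report$stages$enrich <- list(
      n_terms_tested = nrow(enr),
      n_significant = if ("significant" %in% names(enr))
        sum(enr$significant) else 0L)
    log_stage("enrich", report$stages$enrich$n_significant,
              " significant terms")
  }

  ## ---- ppi -------------------------------------------------------------
  pp_path <- file.path(ind, "string_edges.tsv")
  ppi_edges <- NULL
  if ("ppi" %in% stages && explicit && !file.exists(pp_path))
    stage_input("ppi", pp_path)
  if ("ppi" %in% stages && file.exists(pp_path)) {
    string_tab <- read_string_edges(pp_path)
    ppi_edges <- ppi_filter(string_tab, score_threshold = config$ppi_score)
    tg <- unique(targets_tab$gene_id)
    ppi_edges <- ppi_edges[ppi_edges$source %in% tg &
                             ppi_edges$target %in% tg, , drop = FALSE]
    write_tsv(ppi_edges, file.path(outd, "ppi_edges.tsv"))
    report$stages$ppi <- list(n_input = nrow(string_tab),
                              n_retained = nrow(ppi_edges))
    log_stage("ppi", nrow(ppi_edges), " edges above score ",
              config$ppi_score)
  }

  ## ---- export ----------------------------------------------------------
  if ("export" %in% stages) {
    edges <- network_edges()
    if (!is.null(targets_tab) && nrow(targets_tab) > 0)
      edges <- rbind(edges, network_edges(targets_tab$lncrna_id,
                                          targets_tab$gene_id,
                                          targets_tab$mode))
    if (!is.null(triads) && nrow(triads) > 0)
      edges <- rbind(edges, triads_to_edges(triads))
    if (!is.null(ppi_edges) && nrow(ppi_edges) > 0)
      edges <- rbind(edges, ppi_edges)
    edges <- unique(edges)
    class(edges) <- c("network_edges", "data.frame")
    write_network(edges, file.path(outd, "network.sif"), "SIF")
    write_network(edges, file.path(outd, "network.graphml"), "GraphML")
    report$stages$export <- list(n_edges = nrow(edges))
    log_stage("export", nrow(edges), " network edges")
  }

  jsonlite::write_json(report, file.path(outd, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("done", "elapsed ",
            round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1),
            " s")
  invisible(report)
}
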