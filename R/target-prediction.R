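#' Cis target genes by genomic proximity
#'
#' A gene is a cis target of a lncRNA when both lie on the same chromosome
#' and the gap between their genomic spans (first exon start to last exon
#' end) is at most `window_bp`. The gap is the number of bases strictly
#' between the spans: overlapping or adjacent spans have gap 0. Strand is
#' ignored and the cutoff is inclusive (a gap of exactly `window_bp`
#' qualifies). Implemented with GenomicRanges overlap machinery.
#'
#' @param lncrnas,genes [transcript_set]s sharing a coordinate system.
#' @param window_bp window in base pairs (default 100000, i.e. 100 kb
#'   upstream and downstream).
#' @return data.frame `lncrna_id`, `gene_id`, `mode` (`"cis"`),
#'   `distance_bp`.
#' @export
cis_targets <- function(lncrnas, genes, window_bp = 100000L) {
  stopifnot(inherits(lncrnas, "transcript_set"),
            inherits(genes, "transcript_set"))
  empty <- data.frame(lncrna_id = character(), gene_id = character(),
                      mode = character(), distance_bp = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(lncrnas) == 0L || nrow(genes) == 0L) return(empty)
  sl <- tx_span(lncrnas); sg <- tx_span(genes)
  seqlv <- union(sl$chrom, sg$chrom)
  grl <- GenomicRanges::GRanges(factor(sl$chrom, seqlv),
                                IRanges::IRanges(sl$start, sl$end))
  grg <- GenomicRanges::GRanges(factor(sg$chrom, seqlv),
                                IRanges::IRanges(sg$start, sg$end))
  hits <- GenomicRanges::findOverlaps(grl, grg, maxgap = window_bp,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(grl[qi], grg[si], ignore.strand = TRUE)
  keep <- d <= window_bp & sl$transcript_id[qi] != sg$transcript_id[si]
  out <- data.frame(lncrna_id = sl$transcript_id[qi][keep],
                    gene_id = sg$transcript_id[si][keep],
                    mode = "cis",
                    distance_bp = as.integer(d[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
}

#' Trans target genes by expression correlation
#'
#' A gene is a trans target of a lncRNA when the Pearson correlation of
#' their expression across the samples exceeds `r_threshold` (strictly
#' greater). The threshold is signed by default — only positive
#' co-expression qualifies — because the selection rule is `r > threshold`,
#' not `|r| > threshold`; set `use_abs = TRUE` for absolute-value mode.
#' Features with zero variance are skipped with a warning.
#'
#' @param expr an [expression_matrix].
#' @param lncrna_ids,gene_ids feature ids, all present in `expr`.
#' @param r_threshold correlation cutoff (default 0.95; the stricter 0.98
#'   used for pathway-focused views is the same parameter).
#' @param use_abs compare `|r|` instead of signed `r`.
#' @return data.frame `lncrna_id`, `gene_id`, `mode` (`"trans"`), `r`.
#' @export
trans_targets <- function(expr, lncrna_ids, gene_ids, r_threshold = 0.95,
                          use_abs = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  lncrna_ids <- unique(as.character(lncrna_ids))
  gene_ids <- unique(as.character(gene_ids))
  missing <- setdiff(c(lncrna_ids, gene_ids), rownames(expr$fpkm))
  if (length(missing) > 0)
    stop("feature id(s) missing from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  empty <- data.frame(lncrna_id = character(), gene_id = character(),
                      mode = character(), r = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lncrna_ids) == 0L || length(gene_ids) == 0L) return(empty)
  xm <- t(expr$fpkm[lncrna_ids, , drop = FALSE])
  ym <- t(expr$fpkm[gene_ids, , drop = FALSE])
  zero_x <- apply(xm, 2L, stats::sd) == 0
  zero_y <- apply(ym, 2L, stats::sd) == 0
  if (any(zero_x) || any(zero_y))
    warning("skipping zero-variance feature(s): ",
            paste(c(colnames(xm)[zero_x], colnames(ym)[zero_y]),
                  collapse = ", "))
  xm <- xm[, !zero_x, drop = FALSE]; ym <- ym[, !zero_y, drop = FALSE]
  if (ncol(xm) == 0L || ncol(ym) == 0L) return(empty)
  r <- stats::cor(xm, ym)               # lncrna x gene
  crit <- if (use_abs) abs(r) else r
  hit <- which(crit > r_threshold &
                 outer(colnames(xm), colnames(ym), `!=`), arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  out <- data.frame(lncrna_id = colnames(xm)[hit[, 1L]],
                    gene_id = colnames(ym)[hit[, 2L]],
                    mode = "trans",
                    r = r[hit],
                    stringsAsFactors = FALSE)
  out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
}
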