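#' Per-feature fold change between two stages
#'
#' Fold change is the ratio of pseudocount-shifted stage means of FPKM,
#' numerator stage over denominator stage:
#' `FC = (mean_num + pseudocount) / (mean_den + pseudocount)`.
#'
#' @param expr an [expression_matrix].
#' @param group one row of [comparison_groups()] (or a list with
#'   `numerator`/`denominator` stage labels).
#' @param pseudocount added to both means (default 0.01) so features absent
#'   in one stage get a finite ratio; with both means zero the ratio is 1.
#' @return data.frame `feature_id`, `fold_change`, `log2fc`.
#' @export
fold_change <- function(expr, group, pseudocount = 0.01) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (any(expr$fpkm < 0)) stop("negative FPKM")
  num <- expr$fpkm[, stage_samples(expr, group$numerator), drop = FALSE]
  den <- expr$fpkm[, stage_samples(expr, group$denominator), drop = FALSE]
  fc <- (rowMeans(num) + pseudocount) / (rowMeans(den) + pseudocount)
  data.frame(feature_id = rownames(expr$fpkm),
             fold_change = unname(fc), log2fc = unname(log2(fc)),
             stringsAsFactors = FALSE)
}

#' Negative-binomial Wald test between two stages
#'
#' A small-sample stand-in for count-based differential expression testing:
#' the statistic is the difference of log group means over its standard
#' error under a negative-binomial model, with a per-feature dispersion
#' estimated by method of moments from the pooled within-group variance
#' (`phi = (s2_pooled - m_pooled) / m_pooled^2`, floored at 1e-8). Using the
#' delta method, `Var(log mean) ~ (1/m + phi)/n` per group. Two-sided
#' p-values come from a t reference with `n1 + n2 - 1` degrees of freedom, a
#' small-sample choice calibrated so the null rejection rate at alpha = 0.05
#' sits near nominal with 3 replicates per group (a normal reference is
#' markedly anticonservative there). Group means of zero are floored at
#' `1/n` replicates before taking logs. This reproduces the thresholding
#' behaviour of negative-binomial DE pipelines, not any particular tool's
#' numbers.
#'
#' @param counts an [expression_matrix] with a `counts` component.
#' @param group one row of [comparison_groups()].
#' @return data.frame `feature_id`, `stat`, `p`.
#' @export
nb_test <- function(counts, group) {
  stopifnot(inherits(counts, "expression_matrix"))
  cm <- counts$counts
  if (is.null(cm)) stop("expression matrix has no counts")
  if (any(cm != round(cm))) stop("counts must be integers")
  c1 <- cm[, stage_samples(counts, group$numerator), drop = FALSE]
  c2 <- cm[, stage_samples(counts, group$denominator), drop = FALSE]
  n1 <- ncol(c1); n2 <- ncol(c2)
  m1 <- rowMeans(c1); m2 <- rowMeans(c2)
  v1 <- apply(c1, 1L, stats::var); v2 <- apply(c2, 1L, stats::var)
  s2p <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mp <- (m1 + m2) / 2
  phi <- pmax((s2p - mp) / mp^2, 1e-8)
  phi[!is.finite(phi)] <- 1e-8       # mp = 0: no information
  f1 <- pmax(m1, 1 / n1); f2 <- pmax(m2, 1 / n2)
  se <- sqrt((1 / f1 + phi) / n1 + (1 / f2 + phi) / n2)
  w <- (log(f1) - log(f2)) / se
  p <- 2 * stats::pt(-abs(w), df = n1 + n2 - 1)
  data.frame(feature_id = rownames(cm), stat = unname(w), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]), order-preserving with
#' the input vector.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Flag differentially expressed features
#'
#' Two grades are kept, mirroring the two thresholds used for DE lists
#' versus ceRNA construction:
#' * `is_de`: `q < 0.05` (strict) and fold change at least 1.7 in either
#'   direction (`FC >= 1.7` or `FC <= 1/1.7`, boundary inclusive);
#' * `is_cerna_grade`: `q < 0.05` and `|log2FC| >= 1` (i.e. 2-fold).
#'
#' @param results data.frame with columns `feature_id`, `fold_change`,
#'   `log2fc`, `p`, `q` (e.g. from [de_table()] internals).
#' @param fc_threshold linear fold-change threshold for `is_de`
#'   (default 1.7, inclusive, direction-symmetric).
#' @param cerna_log2fc `|log2FC|` threshold for `is_cerna_grade`
#'   (default 1, inclusive).
#' @param q_threshold FDR threshold (default 0.05, strict).
#' @return `results` with logical columns `is_de` and `is_cerna_grade`
#'   appended.
#' @export
call_de <- function(results, fc_threshold = 1.7, cerna_log2fc = 1,
                    q_threshold = 0.05) {
  fc <- results$fold_change
  results$is_de <- (fc >= fc_threshold | fc <= 1 / fc_threshold) &
    results$q < q_threshold
  results$is_cerna_grade <- abs(results$log2fc) >= cerna_log2fc &
    results$q < q_threshold
  results
}

#' Differential expression table for one or all comparison groups
#'
#' Combines [fold_change()] (on FPKM), [nb_test()] (on counts),
#' [bh_adjust()] within each group, and [call_de()].
#'
#' @param expr an [expression_matrix] with counts.
#' @param groups data.frame from [comparison_groups()] (default: all six).
#' @param pseudocount passed to [fold_change()].
#' @param ... thresholds passed to [call_de()].
#' @return data.frame with columns `feature_id`, `group`, `fold_change`,
#'   `log2fc`, `p`, `q`, `is_de`, `is_cerna_grade`.
#' @export
de_table <- function(expr, groups = comparison_groups(), pseudocount = 0.01,
                     ...) {
  out <- lapply(seq_len(nrow(groups)), function(gi) {
    g <- groups[gi, ]
    fc <- fold_change(expr, g, pseudocount = pseudocount)
    tst <- nb_test(expr, g)
    stopifnot(identical(fc$feature_id, tst$feature_id))
    res <- data.frame(feature_id = fc$feature_id, group = g$label,
                      fold_change = fc$fold_change, log2fc = fc$log2fc,
                      p = tst$p, q = bh_adjust(tst$p),
                      stringsAsFactors = FALSE)
    call_de(res, ...)
  })
  do.call(rbind, out)
}

#' Venn membership across the six comparison groups
#'
#' @param de_sets named list mapping each comparison-group label to its DE
#'   feature set; all six labels must be present.
#' @param groups data.frame from [comparison_groups()].
#' @return A list with `membership`: data.frame of per-feature logical
#'   columns (one per group), and `regions`: data.frame `region` (group
#'   labels joined by `&`), `degree`, `count` for every non-empty region of
#'   the 6-set Venn diagram (features falling in exactly that combination).
#' @export
venn_membership <- function(de_sets, groups = comparison_groups()) {
  unknown <- setdiff(names(de_sets), groups$label)
  if (length(unknown) > 0)
    stop("unknown comparison group label(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(groups$label, names(de_sets))
  if (length(missing) > 0)
    stop("missing comparison group(s): ", paste(missing, collapse = ", "))
  de_sets <- de_sets[groups$label]
  feats <- sort(unique(unlist(de_sets)))
  mem <- vapply(de_sets, function(s) feats %in% s,
                logical(length(feats)))
  if (length(feats) == 1L) mem <- matrix(mem, nrow = 1L,
                                         dimnames = list(NULL, groups$label))
  membership <- data.frame(feature_id = feats, mem, check.names = FALSE,
                           stringsAsFactors = FALSE)
  key <- if (length(feats) == 0L) character() else
    apply(mem, 1L, function(r) paste(groups$label[r], collapse = "&"))
  tab <- table(key)
  regions <- data.frame(region = as.character(names(tab)),
                        degree = vapply(strsplit(as.character(names(tab)),
                                                 "&", fixed = TRUE),
                                        length, integer(1)),
                        count = as.integer(tab),
                        stringsAsFactors = FALSE)
  regions <- regions[order(-regions$degree, regions$region), ]
  rownames(regions) <- NULL
  list(membership = membership, regions = regions)
}
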