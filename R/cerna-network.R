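#' Assemble lncRNA-miRNA-mRNA ceRNA triads
#'
#' A triad (l, m, g) is emitted when the miRNA m is differentially expressed
#' in the comparison group, m targets both the lncRNA l and the mRNA g, and
#' l and g are both ceRNA-grade DE in the group (q < 0.05 and |log2FC| >= 1
#' upstream). The output is the relational join of the three membership
#' sets with the two target-pair tables, deduplicated and in lexicographic
#' (lncRNA, miRNA, mRNA) order. Target pairs referencing features outside
#' the DE sets simply fail the join; their count is reported as the
#' `n_excluded_*` attributes.
#'
#' An optional anticorrelation filter restricts triads to those whose miRNA
#' changed in the direction opposite to both partners; it is off by default
#' because the construction rule does not require it.
#'
#' @param de_lncrnas,de_mrnas character vectors of ceRNA-grade DE feature
#'   ids for the group.
#' @param de_mirnas character vector of DE miRNA ids for the group.
#' @param mirna_lncrna_pairs,mirna_mrna_pairs data.frames with `mirna_id`
#'   and `target_id` columns (e.g. from [predict_targets()]).
#' @param group the comparison-group label recorded on the output.
#' @param direction optional named numeric vectors (`lncrna`, `mirna`,
#'   `mrna` log2FCs) enabling the anticorrelation filter; `NULL` (default)
#'   disables it.
#' @return data.frame `lncrna_id`, `mirna_id`, `mrna_id`, `group`, with
#'   attributes `n_excluded_lncrna_pairs` / `n_excluded_mrna_pairs`.
#' @export
build_triads <- function(de_lncrnas, de_mrnas, de_mirnas,
                         mirna_lncrna_pairs, mirna_mrna_pairs,
                         group = "global", direction = NULL) {
  need <- function(df, nm) {
    stopifnot(is.data.frame(df), all(c("mirna_id", "target_id") %in% names(df)))
    unique(df[, c("mirna_id", "target_id")])
  }
  pl <- need(mirna_lncrna_pairs)
  pg <- need(mirna_mrna_pairs)
  keep_l <- pl$mirna_id %in% de_mirnas & pl$target_id %in% de_lncrnas
  keep_g <- pg$mirna_id %in% de_mirnas & pg$target_id %in% de_mrnas
  n_excl_l <- sum(!keep_l); n_excl_g <- sum(!keep_g)
  pl <- pl[keep_l, , drop = FALSE]
  pg <- pg[keep_g, , drop = FALSE]
  tri <- merge(pl, pg, by = "mirna_id", suffixes = c(".l", ".g"))
  out <- unique(data.frame(lncrna_id = tri$target_id.l,
                           mirna_id = tri$mirna_id,
                           mrna_id = tri$target_id.g,
                           group = rep_len(group, nrow(tri)),
                           stringsAsFactors = FALSE))
  if (!is.null(direction)) {
    md <- direction$mirna[out$mirna_id]
    ld <- direction$lncrna[out$lncrna_id]
    gd <- direction$mrna[out$mrna_id]
    out <- out[!is.na(md) & !is.na(ld) & !is.na(gd) &
                 sign(md) != 0 & sign(md) == -sign(ld) &
                 sign(md) == -sign(gd), , drop = FALSE]
  }
  out <- out[order(out$lncrna_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_lncrna_pairs") <- n_excl_l
  attr(out, "n_excluded_mrna_pairs") <- n_excl_g
  out
}

#' Count ceRNA networks per gene
#'
#' The counting unit is the distinct (lncRNA, miRNA) pair among a gene's
#' triads — so a gene whose triads involve 2 miRNAs and 12 lncRNAs in 13
#' distinct combinations is "involved in 13 ceRNA networks".
#'
#' @param triads data.frame from [build_triads()].
#' @return Named integer vector, `mrna_id` -> network count (genes with no
#'   triads are absent).
#' @export
per_gene_network_count <- function(triads) {
  if (nrow(triads) == 0L)
    return(stats::setNames(integer(), character()))
  u <- unique(triads[, c("lncrna_id", "mirna_id", "mrna_id")])
  counts <- table(u$mrna_id)
  stats::setNames(as.integer(counts), names(counts))
}

#' Export ceRNA triads as a network edge table
#'
#' Each triad contributes a `mirna_lncrna` and a `mirna_mrna` edge, ready
#' for [write_network()] (SIF/GraphML for Cytoscape-style visualization).
#'
#' @param triads data.frame from [build_triads()].
#' @return A [network_edges] table (deduplicated).
#' @export
triads_to_edges <- function(triads) {
  if (nrow(triads) == 0L) return(network_edges())
  e1 <- data.frame(source = triads$mirna_id, target = triads$lncrna_id,
                   edge_type = "mirna_lncrna", stringsAsFactors = FALSE)
  e2 <- data.frame(source = triads$mirna_id, target = triads$mrna_id,
                   edge_type = "mirna_mrna", stringsAsFactors = FALSE)
  e <- unique(rbind(e1, e2))
  network_edges(e$source, e$target, e$edge_type)
}
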