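#' Hypergeometric over-representation test for gene sets
#'
#' For each term, with universe size N, term size K (after intersecting the
#' term with the universe), query size n and overlap k, the p-value is the
#' hypergeometric upper tail P(X >= k). Terms empty after intersection are
#' skipped. Benjamini-Hochberg adjustment is applied within each namespace;
#' a term is significant when q < 0.05. The plain upper tail is a
#' transparent stand-in for DAVID's modified Fisher (EASE) score; EASE-style
#' subtraction (testing k - 1) is available behind `ease`.
#'
#' @param query character vector of gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of background gene ids.
#' @param terms data.frame with columns `term_id`, `term_name`, `namespace`
#'   (`GO_BP`, `GO_MF`, `GO_CC`, `pathway`), `members` (list column of id
#'   vectors), e.g. from [read_gene_sets()].
#' @param q_threshold significance threshold on q (default 0.05, strict).
#' @param ease apply the EASE k-1 correction.
#' @return data.frame `term_id`, `term_name`, `namespace`, `k`, `K`, `n`,
#'   `N`, `p`, `q`, `significant`, with attribute `test` naming the
#'   implemented test.
#' @export
enrich <- function(query, universe, terms, q_threshold = 0.05, ease = FALSE) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  outside <- setdiff(query, universe)
  if (length(outside) > 0)
    stop("query gene(s) not in universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  stopifnot(is.data.frame(terms),
            all(c("term_id", "term_name", "namespace", "members") %in%
                  names(terms)))
  N <- length(universe); n <- length(query)
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    members <- intersect(terms$members[[i]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)                  # term absent from universe
    k <- length(intersect(members, query))
    kk <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(kk - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               namespace = terms$namespace[i],
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    out <- data.frame(term_id = character(), term_name = character(),
                      namespace = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "test") <- "hypergeometric upper tail, BH per namespace"
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (ns in unique(out$namespace))
    out$q[out$namespace == ns] <- bh_adjust(out$p[out$namespace == ns])
  out$significant <- out$q < q_threshold
  out <- out[order(out$namespace, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "test") <- "hypergeometric upper tail, BH per namespace"
  out
}

#' Read a GMT-style gene-set table
#'
#' Tab-separated lines: `term_id<TAB>term_name<TAB>namespace<TAB>member...`
#' (one term per line, two or more members columns allowed).
#'
#' @param path file path.
#' @return data.frame with `term_id`, `term_name`, `namespace` and a
#'   `members` list column.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L))
    stop("gene-set line with fewer than 4 fields")
  out <- data.frame(term_id = vapply(parts, `[`, "", 1L),
                    term_name = vapply(parts, `[`, "", 2L),
                    namespace = vapply(parts, `[`, "", 3L),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$term_id)) stop("duplicate term_id")
  out$members <- lapply(parts, function(x) unique(x[-(1:3)]))
  out
}

#' Write gene sets in the GMT-style layout read by [read_gene_sets()]
#' @param terms data.frame as returned by [read_gene_sets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(terms, path) {
  lines <- vapply(seq_len(nrow(terms)), function(i)
    paste(c(terms$term_id[i], terms$term_name[i], terms$namespace[i],
            terms$members[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter STRING-format protein-protein interactions by combined score
#'
#' Keeps edges with `combined_score` strictly greater than the threshold
#' (an edge at exactly 700 is excluded at the default), deduplicates them
#' as unordered pairs, and converts the 0-1000 integer score to a 0-1
#' weight.
#'
#' @param edges data.frame with columns `protein1`, `protein2`,
#'   `combined_score` (integers in 0..1000).
#' @param score_threshold strict lower bound on the combined score
#'   (default 700).
#' @return A [network_edges] table with `edge_type = "ppi"` and
#'   `weight = combined_score / 1000`.
#' @export
ppi_filter <- function(edges, score_threshold = 700L) {
  stopifnot(is.data.frame(edges),
            all(c("protein1", "protein2", "combined_score") %in% names(edges)))
  sc <- edges$combined_score
  if (any(is.na(sc)) || any(sc < 0 | sc > 1000) || any(sc != round(sc)))
    stop("combined_score must be integers in [0, 1000]")
  keep <- edges[sc > score_threshold, , drop = FALSE]
  if (nrow(keep) == 0L) return(network_edges())
  a <- pmin(keep$protein1, keep$protein2)
  b <- pmax(keep$protein1, keep$protein2)
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  network_edges(source = a[first], target = b[first],
                edge_type = "ppi",
                weight = keep$combined_score[first] / 1000)
}

#' Read a STRING-format edge table
#' @param path TSV with header `protein1`, `protein2`, `combined_score`.
#' @return data.frame with those columns.
#' @export
read_string_edges <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(tab)))
    stop("STRING table must have columns: ", paste(need, collapse = ", "))
  tab
}
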