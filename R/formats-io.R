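#' Read transcript models from a GTF file
#'
#' Parses exon features (via rtracklayer) into a [transcript_set]. Exons are
#' grouped by `transcript_id`, sorted by start, and coordinates kept 1-based
#' closed. A `class_code` attribute is honoured when present; transcripts
#' without one get `"="` (an annotated match), since reference GTFs carry no
#' class code for known transcripts. A `biotype` attribute is honoured the
#' same way (default `"unclassified"`).
#'
#' @param path path to a GTF file.
#' @return A [transcript_set].
#' @seealso [write_gtf()]
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1]]
    stop("malformed GTF line ", bad, " in ", path,
         " (expected 9 tab-separated fields)")
  }
  if (!any(body)) {
    return(transcript_set(character(), character(), character(), character(),
                          list(), list()))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L)
    return(transcript_set(character(), character(), character(), character(),
                          list(), list()))
  md <- S4Vectors::mcols(gr)
  if (is.null(md$transcript_id) || anyNA(md$transcript_id))
    stop("GTF exon feature without transcript_id in ", path)
  tid <- as.character(md$transcript_id)
  ord <- order(match(tid, unique(tid)), GenomicRanges::start(gr))
  gr <- gr[ord]; md <- S4Vectors::mcols(gr); tid <- tid[ord]
  first <- !duplicated(tid)
  cc <- if (!is.null(md$class_code)) as.character(md$class_code) else rep(NA_character_, length(gr))
  cc[is.na(cc)] <- "="
  bt <- if (!is.null(md$biotype)) as.character(md$biotype) else rep(NA_character_, length(gr))
  bt[is.na(bt)] <- "unclassified"
  gid <- if (!is.null(md$gene_id)) as.character(md$gene_id) else tid
  transcript_set(
    transcript_id = tid[first],
    gene_id = gid[first],
    chrom = as.character(GenomicRanges::seqnames(gr))[first],
    strand = as.character(GenomicRanges::strand(gr))[first],
    exon_starts = split(GenomicRanges::start(gr), factor(tid, levels = tid[first])),
    exon_ends = split(GenomicRanges::end(gr), factor(tid, levels = tid[first])),
    class_code = cc[first],
    biotype = bt[first])
}

#' Write transcript models to a GTF file
#'
#' One `exon` feature line per exon, carrying `gene_id`, `transcript_id`,
#' `class_code` and `biotype` attributes, so [read_gtf()] round-trips all
#' fields.
#'
#' @param tx a [transcript_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(tx, path) {
  stopifnot(inherits(tx, "transcript_set"))
  n_ex <- tx_n_exons(tx)
  if (nrow(tx) == 0L) {
    writeLines("##gff-version 2", path)
    return(invisible(path))
  }
  idx <- rep(seq_len(nrow(tx)), n_ex)
  gr <- GenomicRanges::GRanges(
    seqnames = tx$chrom[idx],
    ranges = IRanges::IRanges(start = unlist(tx$exon_starts),
                              end = unlist(tx$exon_ends)),
    strand = tx$strand[idx],
    type = "exon",
    gene_id = tx$gene_id[idx],
    transcript_id = tx$transcript_id[idx],
    class_code = tx$class_code[idx],
    biotype = tx$biotype[idx])
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a feature-by-sample expression table
#'
#' Reads a TSV whose header row names the samples and whose first column
#' holds feature ids, aligning columns to the given design.
#'
#' @param path path to a tab-separated file.
#' @param design data.frame with `sample_id`, `stage`, `replicate` (see
#'   [expression_matrix()]).
#' @param counts_path optional path to a matching raw-count TSV.
#' @return An [expression_matrix].
#' @export
read_expression_table <- function(path, design, counts_path = NULL) {
  read_one <- function(p) {
    tab <- utils::read.delim(p, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("expression table has no sample columns: ", p)
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
      stop("duplicate feature id in ", p, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
  fpkm <- read_one(path)
  missing <- setdiff(design$sample_id, colnames(fpkm))
  if (length(missing) > 0)
    stop("samples in design missing from table: ",
         paste(missing, collapse = ", "))
  counts <- if (!is.null(counts_path)) read_one(counts_path)
  expression_matrix(fpkm[, design$sample_id, drop = FALSE], design,
                    counts = if (!is.null(counts)) counts[, design$sample_id, drop = FALSE])
}

#' Write the FPKM (or count) table of an expression matrix as TSV
#'
#' @param expr an [expression_matrix].
#' @param path output path.
#' @param what `"fpkm"` or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path, what = c("fpkm", "counts")) {
  what <- match.arg(what)
  m <- expr[[what]]
  if (is.null(m)) stop("expression matrix has no ", what)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read nucleotide sequences from a FASTA file
#'
#' U is normalized to T and case is upper-cased on load (see
#' [sequence_set()]).
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return A [sequence_set].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  v <- as.character(ss)
  names(v) <- sub("\\s.*$", "", names(ss))
  sequence_set(v)
}

#' Write a sequence set to FASTA
#'
#' @param seqs a [sequence_set] (or named character vector).
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(seqs))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write a network to SIF or GraphML
#'
#' SIF lines are `source<TAB>edge_type<TAB>target`, the format Cytoscape
#' imports directly; GraphML (via igraph) carries `edge_type` and `weight`
#' as edge attributes.
#'
#' @param edges a [network_edges] table (may be empty).
#' @param path output path.
#' @param format `"SIF"` or `"GraphML"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("SIF", "GraphML")) {
  if (length(format) != 1L || !format %in% c("SIF", "GraphML"))
    stop("unknown network format: ", paste(format, collapse = "/"),
         " (use \"SIF\" or \"GraphML\")")
  stopifnot(is.data.frame(edges))
  if (format == "SIF") {
    lines <- if (nrow(edges) == 0L) character() else
      paste(edges$source, edges$edge_type, edges$target, sep = "\t")
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$source, to = edges$target,
                 edge_type = edges$edge_type,
                 weight_attr = edges$weight,
                 stringsAsFactors = FALSE),
      directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path path to a SIF or GraphML file.
#' @param format `"SIF"` or `"GraphML"`.
#' @return A [network_edges] table.
#' @export
read_network <- function(path, format = c("SIF", "GraphML")) {
  if (length(format) != 1L || !format %in% c("SIF", "GraphML"))
    stop("unknown network format")
  if (format == "SIF") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) return(network_edges())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3L)) stop("malformed SIF line")
    network_edges(source = vapply(parts, `[`, "", 1L),
                  target = vapply(parts, `[`, "", 3L),
                  edge_type = vapply(parts, `[`, "", 2L))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    df <- igraph::as_data_frame(g, what = "edges")
    if (nrow(df) == 0L) return(network_edges())
    w <- if ("weight_attr" %in% names(df)) as.numeric(df$weight_attr) else NA_real_
    w[is.nan(w)] <- NA_real_
    network_edges(source = df$from, target = df$to,
                  edge_type = df$edge_type, weight = w)
  }
}

#' Read a coding-potential verdicts table
#'
#' TSV with columns `transcript_id`, `cpc`, `pfam`, `phylocsf`, `cnci`;
#' verdict values are `"coding"` or `"noncoding"` (one row per transcript,
#' as produced by running the four external predictors).
#'
#' @param path path to the TSV.
#' @return data.frame with the five columns, validated.
#' @export
read_verdicts <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_verdicts(tab)
}

validate_verdicts <- function(tab) {
  need <- c("transcript_id", "cpc", "pfam", "phylocsf", "cnci")
  if (!all(need %in% names(tab)))
    stop("verdicts table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  if (anyDuplicated(tab$transcript_id))
    stop("duplicate transcript_id in verdicts table")
  vals <- unlist(tab[, -1L])
  if (length(vals) > 0 && !all(vals %in% c("coding", "noncoding")))
    stop("verdict values must be 'coding' or 'noncoding'")
  tab
}

#' Write a plain TSV (tab-separated, header, no quoting)
#'
#' Shared writer for all the pipeline's tabular outputs (DE results, target
#' pairs, triads, enrichment results, reports).
#'
#' @param df a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain TSV written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
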