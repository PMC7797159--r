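#' Construct a transcript set
#'
#' A `transcript_set` is the package's container for stranded, exon-structured
#' transcript models. It is a `data.frame` with one row per transcript and
#' list columns holding the exon intervals, so base-R subsetting works
#' throughout. Coordinates are 1-based closed intervals (GTF convention)
#' everywhere in the package.
#'
#' @param transcript_id character vector, unique within the set.
#' @param gene_id character vector of parent gene ids.
#' @param chrom character vector of chromosome names.
#' @param strand character vector, `"+"` or `"-"`.
#' @param exon_starts list of integer vectors (1-based starts, sorted).
#' @param exon_ends list of integer vectors (closed ends, same lengths).
#' @param class_code single-character cuffcompare-style class code per
#'   transcript (e.g. `"="`, `"u"`, `"x"`, `"j"`). Defaults to `"="`.
#' @param biotype one of `"mRNA"`, `"lncRNA_annotated"`, `"lncRNA_novel"`,
#'   `"TUCP"`, `"unclassified"`. Defaults to `"unclassified"`.
#'
#' @return A `data.frame` of class `transcript_set` with columns
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `class_code`, `biotype`
#'   and list columns `exon_starts`, `exon_ends`.
#' @examples
#' tx <- transcript_set("t1", "g1", "chr1", "+",
#'                      list(c(100L, 500L)), list(c(200L, 900L)))
#' tx_length(tx)  # 101 + 401
#' @export
transcript_set <- function(transcript_id, gene_id, chrom, strand,
                           exon_starts, exon_ends,
                           class_code = "=", biotype = "unclassified") {
  n <- length(transcript_id)
  stopifnot(length(exon_starts) == n, length(exon_ends) == n)
  gene_id <- rep_len(gene_id, n)
  chrom <- rep_len(chrom, n)
  strand <- rep_len(strand, n)
  if (anyDuplicated(transcript_id))
    stop("duplicate transcript_id: ",
         paste(unique(transcript_id[duplicated(transcript_id)]), collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  biotypes <- c("mRNA", "lncRNA_annotated", "lncRNA_novel", "TUCP", "unclassified")
  biotype <- rep_len(biotype, n)
  class_code <- rep_len(class_code, n)
  if (n > 0 && !all(biotype %in% biotypes))
    stop("unknown biotype")
  for (i in seq_len(n)) {
    s <- as.integer(exon_starts[[i]]); e <- as.integer(exon_ends[[i]])
    if (length(s) == 0L) stop("transcript ", transcript_id[i], ": no exons")
    if (length(s) != length(e))
      stop("transcript ", transcript_id[i], ": exon start/end length mismatch")
    if (any(s < 1L)) stop("transcript ", transcript_id[i], ": exon start < 1")
    if (any(e < s)) stop("transcript ", transcript_id[i], ": exon start > end")
    o <- order(s)
    s <- s[o]; e <- e[o]
    if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
      stop("transcript ", transcript_id[i], ": overlapping exons")
    exon_starts[[i]] <- s; exon_ends[[i]] <- e
  }
  out <- data.frame(transcript_id = as.character(transcript_id),
                    gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    strand = as.character(strand),
                    class_code = as.character(class_code),
                    biotype = biotype,
                    stringsAsFactors = FALSE)
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' @describeIn transcript_set Spliced transcript length (sum of exon widths).
#' @param x a `transcript_set`.
#' @export
tx_length <- function(x) {
  vapply(seq_len(nrow(x)),
         function(i) sum(x$exon_ends[[i]] - x$exon_starts[[i]] + 1L),
         integer(1))
}

#' @describeIn transcript_set Number of exons per transcript.
#' @export
tx_n_exons <- function(x) {
  lengths(x$exon_starts)
}

#' @describeIn transcript_set Genomic span (first exon start to last exon end)
#'   as a data.frame with `chrom`, `start`, `end`.
#' @export
tx_span <- function(x) {
  data.frame(transcript_id = x$transcript_id,
             chrom = x$chrom,
             start = vapply(x$exon_starts, function(s) s[1L], integer(1)),
             end = vapply(x$exon_ends, function(e) e[length(e)], integer(1)),
             stringsAsFactors = FALSE)
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set with", nrow(x), "transcripts\n")
  if (nrow(x) > 0) {
    tab <- table(x$biotype)
    cat("biotypes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct an expression matrix with stage/replicate design
#'
#' Holds FPKM (and optionally raw count) values for features across a staged
#' design of 4 developmental stages x 3 replicates (12 samples).
#'
#' @param fpkm numeric matrix, features x samples, non-negative, with row and
#'   column names.
#' @param design data.frame with columns `sample_id`, `stage`, `replicate`;
#'   every stage must have exactly 3 samples.
#' @param counts optional non-negative integer matrix with identical dimnames.
#'
#' @return A list of class `expression_matrix` with elements `fpkm`, `counts`,
#'   `design`.
#' @export
expression_matrix <- function(fpkm, design, counts = NULL) {
  fpkm <- as.matrix(fpkm)
  if (is.null(rownames(fpkm)) || is.null(colnames(fpkm)))
    stop("fpkm needs row (feature) and column (sample) names")
  if (anyDuplicated(rownames(fpkm)))
    stop("duplicate feature id: ",
         paste(unique(rownames(fpkm)[duplicated(rownames(fpkm))]), collapse = ", "))
  if (any(fpkm < 0)) stop("negative FPKM value")
  design <- as.data.frame(design)
  stopifnot(all(c("sample_id", "stage", "replicate") %in% names(design)))
  if (!setequal(colnames(fpkm), design$sample_id) ||
      ncol(fpkm) != nrow(design))
    stop("sample columns do not match design sample_id")
  per_stage <- table(design$stage)
  if (any(per_stage != 3L))
    stop("every stage must have exactly 3 samples")
  fpkm <- fpkm[, design$sample_id, drop = FALSE]
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (!identical(dim(counts), dim(fpkm)))
      stop("counts dimensions differ from fpkm")
    if (any(counts < 0) || any(counts != round(counts)))
      stop("counts must be non-negative integers")
    counts <- counts[, design$sample_id, drop = FALSE]
    storage.mode(counts) <- "integer"
  }
  structure(list(fpkm = fpkm, counts = counts, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$fpkm), "features x", ncol(x$fpkm),
      "samples;", length(unique(x$design$stage)), "stages",
      if (!is.null(x$counts)) "(with counts)" else "(FPKM only)", "\n")
  invisible(x)
}

#' Samples belonging to one stage
#' @param expr an `expression_matrix`.
#' @param stage stage label, e.g. `"W6"`.
#' @return character vector of sample ids.
#' @export
stage_samples <- function(expr, stage) {
  s <- expr$design$sample_id[expr$design$stage == stage]
  if (length(s) == 0L) stop("unknown stage: ", stage)
  s
}

#' Construct a sequence set
#'
#' A named character vector of nucleotide sequences. On construction, U is
#' normalized to T and letters are upper-cased so miRNA (RNA alphabet) and
#' transcript (DNA alphabet) sequences compare directly.
#'
#' @param seqs named character vector over the alphabet `A C G T U N`
#'   (case-insensitive).
#' @return Named character vector of class `sequence_set` (ACGTN alphabet).
#' @export
sequence_set <- function(seqs) {
  if (length(seqs) > 0 &&
      (is.null(names(seqs)) || any(names(seqs) == "")))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  ids <- names(seqs)
  seqs <- chartr("U", "T", toupper(as.character(seqs)))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) stop("empty sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in: ",
         paste(names(seqs)[bad], collapse = ", "))
  structure(seqs, class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set with", length(x), "sequences; total",
      sum(nchar(unclass(x))), "nt\n")
  invisible(x)
}

#' @export
`[.sequence_set` <- function(x, i) {
  structure(NextMethod(), class = "sequence_set")
}

#' Construct a table of network edges
#'
#' @param source,target character vectors of node ids.
#' @param edge_type one of `"cis"`, `"trans"`, `"mirna_lncrna"`,
#'   `"mirna_mrna"`, `"ppi"` per edge.
#' @param weight optional numeric weight per edge (`NA` when absent).
#' @return data.frame of class `network_edges`.
#' @export
network_edges <- function(source = character(), target = character(),
                          edge_type = character(), weight = NA_real_) {
  n <- length(source)
  stopifnot(length(target) == n)
  edge_type <- rep_len(as.character(edge_type), n)
  weight <- rep_len(as.numeric(weight), n)
  types <- c("cis", "trans", "mirna_lncrna", "mirna_mrna", "ppi")
  if (n > 0 && !all(edge_type %in% types))
    stop("edge_type must be one of: ", paste(types, collapse = ", "))
  self_ppi <- edge_type == "ppi" & source == target
  if (any(self_ppi)) stop("self-loop ppi edge: ", source[which(self_ppi)[1]])
  out <- data.frame(source = as.character(source),
                    target = as.character(target),
                    edge_type = edge_type, weight = weight,
                    stringsAsFactors = FALSE)
  class(out) <- c("network_edges", "data.frame")
  out
}
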