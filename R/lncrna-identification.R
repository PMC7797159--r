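# Cuffcompare class codes denoting exonic overlap with reference
# protein-coding annotation; transcripts carrying one are removed at the
# overlap step (unless they match an annotated lncRNA).
OVERLAP_CLASS_CODES <- c("=", "c", "j", "e", "o")

#' Five-step lncRNA screening cascade
#'
#' Screens assembled transcript models for long noncoding RNAs and
#' transcripts of uncertain coding potential (TUCPs):
#'
#' 1. **exon** — remove transcripts with fewer than 2 exons;
#' 2. **length** — remove transcripts with spliced length <= 200 nt
#'    (strictly greater than 200 survives);
#' 3. **overlap** — remove transcripts whose class code marks exonic overlap
#'    with reference annotation (`=`, `c`, `j`, `e`, `o`), except those whose
#'    id is in `annotated_lncrna_ids`, which are routed straight to the
#'    output as annotated lncRNAs;
#' 4. **expression** — remove transcripts whose FPKM never reaches
#'    `fpkm_min` (>= 0.5 is inclusive; the aggregate over the 12 samples is
#'    the maximum by default, configurable);
#' 5. **coding_potential** — transcripts called noncoding by all four
#'    predictors (CPC, PFAM, PhyloCSF, CNCI) become novel lncRNAs; a coding
#'    call from at least one predictor makes a TUCP.
#'
#' @param transcripts a [transcript_set].
#' @param expression an [expression_matrix] covering every transcript that
#'   reaches step 4.
#' @param verdicts verdicts data.frame (`transcript_id`, `cpc`, `pfam`,
#'   `phylocsf`, `cnci`; values `"coding"`/`"noncoding"`); required for every
#'   transcript that reaches step 5.
#' @param annotated_lncrna_ids ids of transcripts matching database-annotated
#'   lncRNAs.
#' @param fpkm_min expression floor (default 0.5, inclusive).
#' @param fpkm_aggregate how FPKM is aggregated across samples before the
#'   floor: `"max"` (default) or `"mean"`.
#'
#' @return A list with `lncrna` (novel lncRNAs), `tucp`, `annotated`
#'   (each a [transcript_set] subset) and `report`, a data.frame with one row
#'   per input transcript: `transcript_id`, `outcome` (`removed`,
#'   `lncRNA_novel`, `TUCP`, `lncRNA_annotated`) and `step` (`exon`,
#'   `length`, `overlap`, `expression`, `coding_potential`, or `""`).
#' @export
filter_cascade <- function(transcripts, expression, verdicts,
                           annotated_lncrna_ids = character(),
                           fpkm_min = 0.5,
                           fpkm_aggregate = c("max", "mean")) {
  stopifnot(inherits(transcripts, "transcript_set"),
            inherits(expression, "expression_matrix"))
  fpkm_aggregate <- match.arg(fpkm_aggregate)
  verdicts <- validate_verdicts(verdicts)
  n <- nrow(transcripts)
  outcome <- rep("removed", n)
  step <- rep("", n)
  alive <- rep(TRUE, n)

  fail_exon <- tx_n_exons(transcripts) < 2L
  step[alive & fail_exon] <- "exon"
  alive <- alive & !fail_exon

  fail_len <- tx_length(transcripts) <= 200L
  step[alive & fail_len] <- "length"
  alive <- alive & !fail_len

  is_annotated <- transcripts$transcript_id %in% annotated_lncrna_ids
  overlaps <- transcripts$class_code %in% OVERLAP_CLASS_CODES
  routed <- alive & is_annotated
  outcome[routed] <- "lncRNA_annotated"
  step[routed] <- ""
  fail_overlap <- overlaps & !is_annotated
  step[alive & fail_overlap] <- "overlap"
  alive <- alive & !fail_overlap & !routed

  idx <- match(transcripts$transcript_id, rownames(expression$fpkm))
  if (any(alive & is.na(idx)))
    stop("no expression for transcript(s): ",
         paste(transcripts$transcript_id[alive & is.na(idx)][1:3],
               collapse = ", "))
  agg <- apply(expression$fpkm[idx[alive], , drop = FALSE], 1L,
               if (fpkm_aggregate == "max") max else mean)
  fail_expr <- rep(FALSE, n)
  fail_expr[alive] <- agg < fpkm_min
  step[alive & fail_expr] <- "expression"
  alive <- alive & !fail_expr

  vi <- match(transcripts$transcript_id, verdicts$transcript_id)
  if (any(alive & is.na(vi)))
    stop("no coding-potential verdicts for transcript(s): ",
         paste(transcripts$transcript_id[alive & is.na(vi)][1:3],
               collapse = ", "))
  vm <- as.matrix(verdicts[vi[alive], c("cpc", "pfam", "phylocsf", "cnci")])
  any_coding <- rowSums(vm == "coding") > 0
  ai <- which(alive)
  outcome[ai[!any_coding]] <- "lncRNA_novel"
  outcome[ai[any_coding]] <- "TUCP"
  step[ai] <- "coding_potential"

  report <- data.frame(transcript_id = transcripts$transcript_id,
                       outcome = outcome, step = step,
                       stringsAsFactors = FALSE)
  list(lncrna = transcripts[outcome == "lncRNA_novel", ],
       tucp = transcripts[outcome == "TUCP", ],
       annotated = transcripts[outcome == "lncRNA_annotated", ],
       report = report)
}

#' Classify novel lncRNAs as lincRNA or antisense
#'
#' Class code `"u"` (intergenic) maps to lincRNA, `"x"` (exonic overlap on
#' the opposite strand) to antisense. Any other class code among the inputs
#' is an error: lncRNAs surviving the cascade are expected to be one of the
#' two types, and an unexpected code is surfaced rather than silently
#' binned.
#'
#' @param lncrnas a [transcript_set] of cascade survivors.
#' @return Named character vector, `transcript_id` -> `"lincRNA"` /
#'   `"antisense"`.
#' @export
classify_lncrna <- function(lncrnas) {
  stopifnot(inherits(lncrnas, "transcript_set"))
  if (nrow(lncrnas) == 0L) return(stats::setNames(character(), character()))
  bad <- !lncrnas$class_code %in% c("u", "x")
  if (any(bad))
    stop("unexpected class code for lncRNA(s): ",
         paste(sprintf("%s(%s)", lncrnas$transcript_id[bad],
                       lncrnas$class_code[bad]), collapse = ", "))
  stats::setNames(ifelse(lncrnas$class_code == "u", "lincRNA", "antisense"),
                  lncrnas$transcript_id)
}

#' Count ATG-initiated open reading frames
#'
#' An ORF is an ATG whose first in-frame stop codon (TAA/TAG/TGA) lies
#' downstream in the same forward frame, with at least `min_codons` codons
#' from the ATG up to (not including) the stop. Every qualifying ATG counts,
#' so nested starts yield multiple ORFs. Only the three forward frames of
#' the spliced sequence are scanned.
#'
#' @param seq a nucleotide string (ACGT).
#' @param min_codons minimum ORF length in codons (default 30, i.e. 90 nt
#'   of coding sequence).
#' @return Integer ORF count.
#' @export
count_orfs <- function(seq, min_codons = 30L) {
  seq <- chartr("U", "T", toupper(seq))
  n <- nchar(seq)
  if (n < (min_codons + 1L) * 3L) return(0L)
  total <- 0L
  for (frame in 0:2) {
    if (n - frame < 3L) next
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    next_stop <- rep(NA_integer_, length(codons))
    last <- NA_integer_
    for (j in rev(seq_along(codons))) {
      if (is_stop[j]) last <- j
      next_stop[j] <- last
    }
    for (i in which(is_atg)) {
      ns <- next_stop[i]
      if (!is.na(ns) && ns > i && (ns - i) >= min_codons) total <- total + 1L
    }
  }
  total
}

#' Per-biotype characterization statistics
#'
#' Summarizes transcript length, exon count, ORF count and expression level
#' by biotype, the standard panels used to contrast lncRNAs against mRNAs
#' (lncRNAs are expected shorter, with fewer exons and ORFs, and lower
#' expression).
#'
#' @param transcripts a [transcript_set] (its `biotype` column defines the
#'   groups).
#' @param sequences a [sequence_set]; transcripts without a sequence get an
#'   `NA` ORF count with a warning.
#' @param expression an [expression_matrix]; per-feature expression is the
#'   mean FPKM across samples.
#' @param length_breaks,orf_breaks,expr_breaks histogram bin edges; the last
#'   bin is open-ended.
#' @return A list with `features`: per-transcript data.frame
#'   (`transcript_id`, `biotype`, `length`, `n_exons`, `n_orfs`,
#'   `mean_fpkm`), and `histograms`: per biotype, binned counts for each
#'   panel with stated break vectors.
#' @export
characterize <- function(transcripts, sequences, expression,
                         length_breaks = c(0, 200, 400, 600, 800, 1000,
                                           1500, 2000, 3000, Inf),
                         orf_breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, 4.5, Inf),
                         expr_breaks = c(0, 0.5, 1, 2, 5, 10, 20, 50, Inf)) {
  stopifnot(inherits(transcripts, "transcript_set"))
  ids <- transcripts$transcript_id
  have_seq <- ids %in% names(sequences)
  if (any(!have_seq))
    warning("no sequence for ", sum(!have_seq),
            " transcript(s); ORF count recorded as NA")
  n_orfs <- rep(NA_integer_, length(ids))
  n_orfs[have_seq] <- vapply(unclass(sequences)[ids[have_seq]],
                             count_orfs, integer(1))
  idx <- match(ids, rownames(expression$fpkm))
  mean_fpkm <- rowMeans(expression$fpkm)[idx]
  features <- data.frame(transcript_id = ids,
                         biotype = transcripts$biotype,
                         length = tx_length(transcripts),
                         n_exons = tx_n_exons(transcripts),
                         n_orfs = n_orfs,
                         mean_fpkm = unname(mean_fpkm),
                         stringsAsFactors = FALSE)
  hist_of <- function(x, breaks) {
    x <- x[!is.na(x)]
    counts <- as.integer(table(cut(x, breaks = breaks, right = TRUE)))
    list(breaks = breaks, counts = counts)
  }
  histograms <- lapply(split(features, features$biotype), function(d) {
    list(length = hist_of(d$length, length_breaks),
         n_exons = hist_of(d$n_exons,
                           c(seq(0.5, max(9.5, max(d$n_exons) + 0.5)), Inf)),
         n_orfs = hist_of(d$n_orfs, orf_breaks),
         mean_fpkm = hist_of(d$mean_fpkm, expr_breaks))
  })
  list(features = features, histograms = histograms)
}
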