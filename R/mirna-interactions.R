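#' Read a miRNA FASTA (mature + precursor records)
#'
#' Records whose id ends in `-pre` are precursor sequences of the matching
#' mature record; all sequences are U-to-T normalized on load.
#'
#' @param path FASTA path.
#' @return data.frame `mirna_id`, `mature_seq`, `precursor_id`,
#'   `precursor_seq` (NA where absent).
#' @export
read_mirna_fasta <- function(path) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  is_pre <- grepl("-pre$", ids)
  mature <- unclass(seqs)[!is_pre]
  out <- data.frame(mirna_id = names(mature), mature_seq = unname(mature),
                    precursor_id = NA_character_,
                    precursor_seq = NA_character_, stringsAsFactors = FALSE)
  for (pid in ids[is_pre]) {
    host <- sub("-pre$", "", pid)
    i <- match(host, out$mirna_id)
    if (is.na(i)) stop("precursor record without mature record: ", pid)
    out$precursor_id[i] <- pid
    out$precursor_seq[i] <- unclass(seqs)[[pid]]
  }
  out
}

#' Predict miRNA targets by canonical seed match
#'
#' A target relation is called when the reverse complement of the miRNA
#' seed (mature positions 2-8, a 7-mer, by default) occurs at least once in
#' the target sequence; all 1-based site start positions are reported. The
#' seed-match rule is a transparent stand-in for canonical miRNA target
#' predictors. Matching is on the DNA alphabet, so U/T representation of
#' the inputs does not matter.
#'
#' @param mirnas data.frame with `mirna_id`, `mature_seq` (>= 8 nt).
#' @param sequences a [sequence_set] of candidate targets.
#' @param target_kind `"lncRNA"` or `"mRNA"`, recorded on the output.
#' @param seed_from,seed_to mature positions delimiting the seed
#'   (default 2..8).
#' @return data.frame `mirna_id`, `target_id`, `target_kind`, `n_sites`,
#'   `site_positions` (comma-joined 1-based starts).
#' @export
predict_targets <- function(mirnas, sequences,
                            target_kind = c("lncRNA", "mRNA"),
                            seed_from = 2L, seed_to = 8L) {
  target_kind <- match.arg(target_kind)
  stopifnot(is.data.frame(mirnas),
            all(c("mirna_id", "mature_seq") %in% names(mirnas)))
  mat <- chartr("U", "T", toupper(mirnas$mature_seq))
  if (any(nchar(mat) < seed_to))
    stop("mature sequence shorter than ", seed_to, " nt: ",
         paste(mirnas$mirna_id[nchar(mat) < seed_to], collapse = ", "))
  targets <- Biostrings::DNAStringSet(unclass(sequences))
  out <- vector("list", nrow(mirnas))
  for (i in seq_len(nrow(mirnas))) {
    seed <- Biostrings::DNAString(substr(mat[i], seed_from, seed_to))
    site <- Biostrings::reverseComplement(seed)
    hits <- Biostrings::vmatchPattern(site, targets)
    starts <- IRanges::start(hits)
    ns <- lengths(starts)
    keep <- which(ns > 0)
    if (length(keep) == 0L) next
    out[[i]] <- data.frame(
      mirna_id = mirnas$mirna_id[i],
      target_id = names(targets)[keep],
      target_kind = target_kind,
      n_sites = ns[keep],
      site_positions = vapply(starts[keep], paste, "", collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(mirna_id = character(), target_id = character(),
                      target_kind = character(), n_sites = integer(),
                      site_positions = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find lncRNAs hosting pre-miRNA sequences by exact homology
#'
#' Reports every exact forward-strand occurrence of each precursor sequence
#' within each lncRNA, with 1-based inclusive coordinates (a 66-nt
#' precursor starting at 309 is reported as the span 309..374). A precursor
#' may hit several host lncRNAs. Reverse-complement search is available but
#' off by default, since hosting is defined by exact forward identity.
#'
#' @param lncrna_seqs a [sequence_set] of lncRNA sequences.
#' @param mirnas data.frame with `precursor_id`, `precursor_seq` (rows with
#'   NA precursor are ignored).
#' @param search_revcomp also search the reverse complement of each
#'   precursor (hits flagged in the `strand` column).
#' @return data.frame `lncrna_id`, `precursor_id`, `start`, `end`, `strand`.
#' @export
precursor_homology <- function(lncrna_seqs, mirnas, search_revcomp = FALSE) {
  stopifnot(is.data.frame(mirnas),
            all(c("precursor_id", "precursor_seq") %in% names(mirnas)))
  pre <- mirnas[!is.na(mirnas$precursor_seq), , drop = FALSE]
  pre <- pre[!duplicated(pre$precursor_id), , drop = FALSE]
  hosts <- Biostrings::DNAStringSet(unclass(lncrna_seqs))
  res <- list()
  scan <- function(pid, pat, strand) {
    hits <- Biostrings::vmatchPattern(pat, hosts)
    st <- IRanges::start(hits); en <- IRanges::end(hits)
    keep <- which(lengths(st) > 0)
    for (k in keep)
      res[[length(res) + 1L]] <<- data.frame(
        lncrna_id = names(hosts)[k], precursor_id = pid,
        start = st[[k]], end = en[[k]], strand = strand,
        stringsAsFactors = FALSE)
  }
  for (j in seq_len(nrow(pre))) {
    pat <- Biostrings::DNAString(chartr("U", "T",
                                        toupper(pre$precursor_seq[j])))
    scan(pre$precursor_id[j], pat, "+")
    if (search_revcomp)
      scan(pre$precursor_id[j], Biostrings::reverseComplement(pat), "-")
  }
  if (length(res) == 0L)
    return(data.frame(lncrna_id = character(), precursor_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$precursor_id, out$lncrna_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
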