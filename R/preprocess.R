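# Quality filtering of raw amplicon reads.

#' Quality-filter amplicon reads
#'
#' Applies the standard screening rules for pyrosequencing-era amplicon data:
#' a minimum length, a cap on ambiguous (non-ACGT) base calls, and a cap on
#' homopolymer run length.  Sequences are uppercased and U is mapped to T
#' before checking.  When several rules fire for one read, the reported
#' reason is the first in the fixed priority order
#' `length > ambiguity > homopolymer`, so rejection accounting is
#' deterministic.
#'
#' @param reads data.frame with `read_id`, `sequence` (and optionally
#'   `sample`), or a named character vector.
#' @param min_length Minimum sequence length in bp (default 300).
#' @param max_ambiguous Maximum number of non-ACGT characters (default 0).
#' @param max_homopolymer Longest allowed single-base run (default 8; a run
#'   of 9 or more is rejected).
#' @return list with elements `kept` (data.frame, input order preserved) and
#'   `rejected` (data.frame with an additional `reason` column, one of
#'   `"length"`, `"ambiguity"`, `"homopolymer"`).
#' @export
quality_filter <- function(reads, min_length = 300, max_ambiguous = 0,
                           max_homopolymer = 8) {
  stopifnot(min_length >= 0, max_ambiguous >= 0, max_homopolymer >= 1)
  reads <- as_read_df(reads)
  seq <- chartr("u", "t", toupper(reads$sequence))
  seq <- chartr("U", "T", seq)
  reads$sequence <- seq

  reason <- rep(NA_character_, nrow(reads))
  too_short <- nchar(seq) < min_length
  reason[too_short] <- "length"

  n_ambig <- nchar(gsub("[ACGT]", "", seq))
  reason[is.na(reason) & n_ambig > max_ambiguous] <- "ambiguity"

  hp <- grepl(sprintf("([ACGT])\\1{%d,}", max_homopolymer), seq, perl = TRUE)
  reason[is.na(reason) & hp] <- "homopolymer"

  list(kept = reads[is.na(reason), , drop = FALSE],
       rejected = cbind(reads[!is.na(reason), , drop = FALSE],
                        reason = reason[!is.na(reason)]))
}

#' Remove reads by name list
#'
#' Drops reads whose id appears in `names` (the mothur accnos convention:
#' typically a chimera list produced by an external detector such as uchime).
#' Names that match no read are ignored but reported via a message.
#'
#' @param reads data.frame of reads (or named character vector).
#' @param names Character vector of read ids to remove, or a path to a file
#'   with one id per line.
#' @return The surviving reads, with attribute `n_removed`.
#' @export
remove_by_name <- function(reads, names) {
  reads <- as_read_df(reads)
  if (length(names) == 1L && file.exists(names))
    names <- readLines(names)
  names <- trimws(names)
  names <- names[nzchar(names)]
  hit <- reads$read_id %in% names
  unmatched <- setdiff(names, reads$read_id)
  if (length(unmatched))
    message(sprintf("remove_by_name: %d name(s) matched no read",
                    length(unmatched)))
  out <- reads[!hit, , drop = FALSE]
  attr(out, "n_removed") <- sum(hit)
  out
}
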