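# Four-tier novelty detection layered on the nucleotide search, the
# translated rescue search, and the LCA assignment, plus conserved-mismatch
# profiling of leaf-assigned read groups.

#' Novelty-detection configuration
#'
#' @param translated_rescue_min_bits Reads without nucleotide hits whose best
#'   translated hit reaches this many bits are called divergent CuMMO rather
#'   than contaminants (default 50).
#' @param divergent_flag_max_bits Reads whose best nucleotide bit score falls
#'   below this threshold are flagged as moderately divergent candidate new
#'   clades (default 150).  Bit-score thresholds are calibrated to the
#'   engine and scoring scheme in use; both are exposed, never hard-coded.
#' @param conserved_mismatch_fraction Fraction of covering reads that must
#'   share the same non-reference base for a column to count (default 0.8).
#' @param conserved_mismatch_min_coverage Minimum reads covering a reference
#'   column before it is considered (default 5).
#' @return A list of class `novelty_config`.
#' @export
novelty_config <- function(translated_rescue_min_bits = 50,
                           divergent_flag_max_bits = 150,
                           conserved_mismatch_fraction = 0.8,
                           conserved_mismatch_min_coverage = 5) {
  stopifnot(translated_rescue_min_bits > 0, divergent_flag_max_bits > 0,
            conserved_mismatch_fraction > 0.5,
            conserved_mismatch_fraction <= 1,
            conserved_mismatch_min_coverage >= 1)
  structure(list(translated_rescue_min_bits = translated_rescue_min_bits,
                 divergent_flag_max_bits = divergent_flag_max_bits,
                 conserved_mismatch_fraction = conserved_mismatch_fraction,
                 conserved_mismatch_min_coverage =
                   conserved_mismatch_min_coverage),
            class = "novelty_config")
}

#' Tier reads by level of novelty
#'
#' Applies the four tiers in precedence order, so every read receives exactly
#' one label:
#'
#' 1. Reads with an empty nucleotide hit set are re-searched in translated
#'    mode: best translated bits at or above the rescue threshold means
#'    `divergent_CuMMO` (a highly divergent homolog whose protein is still
#'    recognizable), otherwise `contaminant`.
#' 2. Reads whose best nucleotide bit score is below
#'    `divergent_flag_max_bits` are `moderately_divergent` -- candidate new
#'    clades -- regardless of where the LCA would place them.
#' 3. Reads whose LCA assignment lands on an internal node are
#'    `internal_node_candidate` (possible new lineages branching at that
#'    node).
#' 4. Remaining reads are `leaf_assigned` and eligible for conserved-mismatch
#'    analysis.
#'
#' @param reads data.frame of reads (or named character vector).
#' @param nt_hits Named list of nucleotide `hit_set`s for these reads (from
#'   [search_nucleotide()] or [parse_external_tabular()]).
#' @param db,tree Reference database and taxonomy.
#' @param ncfg,lcfg,scfg Novelty, LCA and search configurations.
#' @return data.frame of class `novelty_report`: `read_id`, `tier`,
#'   `best_nt_bits`, `best_tx_bits` (NA unless the translated rescue ran),
#'   `node` (LCA node or NA).
#' @export
tier_reads <- function(reads, nt_hits, db, tree = db$tree,
                       ncfg = novelty_config(), lcfg = lca_config(),
                       scfg = search_config()) {
  reads <- as_read_df(reads)
  stopifnot(all(reads$read_id %in% names(nt_hits)))
  no_hit <- vapply(reads$read_id, function(id) nrow(nt_hits[[id]]) == 0L,
                   logical(1))
  tx_bits <- setNames(rep(NA_real_, nrow(reads)), reads$read_id)
  if (any(no_hit)) {
    rescue <- search_translated(reads[no_hit, , drop = FALSE], db, scfg)
    tx_bits[names(rescue)] <- vapply(rescue, function(h)
      if (nrow(h)) max(h$bit_score) else 0, numeric(1))
  }
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    id <- reads$read_id[i]
    h <- nt_hits[[id]]
    if (!nrow(h)) {
      tier <- if (!is.na(tx_bits[id]) &&
                  tx_bits[id] >= ncfg$translated_rescue_min_bits)
        "divergent_CuMMO" else "contaminant"
      return(data.frame(read_id = id, tier = tier, best_nt_bits = NA_real_,
                        best_tx_bits = tx_bits[id], node = NA_character_,
                        stringsAsFactors = FALSE))
    }
    best <- max(h$bit_score)
    a <- assign_lca(h, tree, lcfg)
    tier <- if (best < ncfg$divergent_flag_max_bits) "moderately_divergent"
    else if (a$is_internal) "internal_node_candidate"
    else if (!is.na(a$node)) "leaf_assigned"
    else "moderately_divergent"  # hits exist but all below the LCA floor
    data.frame(read_id = id, tier = tier, best_nt_bits = best,
               best_tx_bits = tx_bits[id], node = a$node,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("novelty_report", "data.frame")
  out
}

#' Conserved-mismatch profile of a leaf-assigned read group
#'
#' Projects each read's alignment onto the coordinates of the shared
#' reference and, for every reference column covered by at least
#' `conserved_mismatch_min_coverage` reads, asks whether the most frequent
#' read base differs from the reference base and is carried by at least
#' `conserved_mismatch_fraction` of the covering reads.  Columns where a read
#' has a gap do not count as covered, and reference gap columns (read
#' insertions) are skipped, so homopolymer indel noise does not inflate the
#' count.  Many conserved mismatches suggest the group is a novel clade most
#' closely related to the assigned taxon.
#'
#' @param hits A list of single hits (or a `hit_set`-style data.frame), one
#'   per read, all against the same reference subject, each carrying `qaln`,
#'   `saln` and `sstart`.
#' @param ncfg A [novelty_config()].
#' @return A list of class `conserved_mismatch_profile`: `reference`,
#'   `n_reads`, `count`, `positions` (1-based reference coordinates), and a
#'   `columns` data.frame (position, ref_base, coverage, modal_base,
#'   modal_fraction) restricted to qualifying columns.
#' @export
conserved_mismatches <- function(hits, ncfg = novelty_config()) {
  if (is.data.frame(hits)) hits <- split(hits, seq_len(nrow(hits)))
  if (!length(hits)) stop("no hits supplied")
  subjects <- unique(vapply(hits, function(h) h$subject[1L], character(1)))
  if (length(subjects) != 1L)
    stop(sprintf("hits span multiple references (%s); split by top reference first",
                 paste(subjects, collapse = ", ")))
  tallies <- list()   # per reference position: table of read bases
  ref_base <- list()
  for (h in hits) {
    qa <- strsplit(h$qaln[1L], "")[[1L]]
    sa <- strsplit(h$saln[1L], "")[[1L]]
    pos <- h$sstart[1L] - 1L
    for (col in seq_along(sa)) {
      if (sa[col] == "-") next   # insertion in read: no reference column
      pos <- pos + 1L
      if (qa[col] == "-") next   # read gap: not covered
      key <- as.character(pos)
      ref_base[[key]] <- sa[col]
      tallies[[key]] <- c(tallies[[key]], qa[col])
    }
  }
  cols <- lapply(names(tallies), function(key) {
    bases <- tallies[[key]]
    if (length(bases) < ncfg$conserved_mismatch_min_coverage) return(NULL)
    tab <- sort(table(bases), decreasing = TRUE)
    modal <- names(tab)[1L]
    frac <- tab[[1L]] / length(bases)
    if (modal != ref_base[[key]] &&
        frac >= ncfg$conserved_mismatch_fraction)
      data.frame(position = as.integer(key), ref_base = ref_base[[key]],
                 coverage = length(bases), modal_base = modal,
                 modal_fraction = frac, stringsAsFactors = FALSE)
    else NULL
  })
  cols <- do.call(rbind, cols[!vapply(cols, is.null, logical(1))])
  if (is.null(cols))
    cols <- data.frame(position = integer(0), ref_base = character(0),
                       coverage = integer(0), modal_base = character(0),
                       modal_fraction = numeric(0), stringsAsFactors = FALSE)
  cols <- cols[order(cols$position), , drop = FALSE]
  rownames(cols) <- NULL
  structure(list(reference = subjects, n_reads = length(hits),
                 count = nrow(cols), positions = cols$position,
                 columns = cols),
            class = "conserved_mismatch_profile")
}

#' @export
print.conserved_mismatch_profile <- function(x, ...) {
  cat(sprintf("conserved_mismatch_profile: %d conserved mismatch column(s) vs %s over %d reads\n",
              x$count, x$reference, x$n_reads))
  invisible(x)
}
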