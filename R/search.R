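# Scored local alignment of reads against the reference database.
#
# Nucleotide mode gates read/reference pairs on an exact shared word (default
# 28 nt, the megablast minimum) and then computes the optimal affine-gap
# local alignment; raw scores are rescaled to bits with Karlin-Altschul
# parameters.  Translated mode compares all six reading frames of read and
# reference (tblastx-style), seeding on exact 3-residue words and extending
# without gaps under BLOSUM62; stop codons truncate extensions.

#' Search configuration
#'
#' Scoring defaults are +1/-2 with affine gaps (open 5, extend 2) and the
#' published ungapped Karlin-Altschul parameters for that scheme
#' (lambda = 1.33, K = 0.621); the translated mode uses BLOSUM62 with its
#' ungapped parameters (lambda = 0.3176, K = 0.134).  Bit scores are
#' `(lambda * raw - ln K) / ln 2`.  Native bit scores are comparable to each
#' other (ranking and thresholds), not numerically to any external engine.
#'
#' @param word_size Exact-match seed length for nucleotide search
#'   (default 28).
#' @param match_reward,mismatch_penalty Nucleotide match/mismatch scores.
#' @param gap_open,gap_extend Affine gap costs (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param lambda,k_const Karlin-Altschul parameters for nucleotide scores.
#' @param min_report_bits Bit-score floor below which hits are dropped.
#' @param tx_word_size Amino-acid seed length for translated search
#'   (default 3).
#' @param tx_lambda,tx_k Karlin-Altschul parameters for translated scores.
#' @param tx_xdrop X-drop termination threshold for ungapped translated
#'   extension (raw score units).
#' @return A list of class `search_config`.
#' @export
search_config <- function(word_size = 28, match_reward = 1,
                          mismatch_penalty = -2, gap_open = 5, gap_extend = 2,
                          lambda = 1.33, k_const = 0.621,
                          min_report_bits = 0, tx_word_size = 3,
                          tx_lambda = 0.3176, tx_k = 0.134, tx_xdrop = 20) {
  stopifnot(word_size >= 4, tx_word_size >= 2, lambda > 0, k_const > 0,
            tx_lambda > 0, tx_k > 0, match_reward > 0, mismatch_penalty < 0)
  structure(list(word_size = word_size, match_reward = match_reward,
                 mismatch_penalty = mismatch_penalty, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, k_const = k_const,
                 min_report_bits = min_report_bits,
                 tx_word_size = tx_word_size, tx_lambda = tx_lambda,
                 tx_k = tx_k, tx_xdrop = tx_xdrop),
            class = "search_config")
}

#' Convert a raw alignment score to bits
#'
#' @param raw Raw alignment score(s).
#' @param lambda,k_const Karlin-Altschul scale and K.
#' @return Bit score(s): `(lambda * raw - ln k_const) / ln 2`.
#' @export
bit_score <- function(raw, lambda = 1.33, k_const = 0.621) {
  (lambda * raw - log(k_const)) / log(2)
}

submat_dna <- function(match, mismatch) {
  m <- matrix(as.integer(mismatch), 128L, 128L)
  for (b in utf8ToInt("ACGT")) m[b + 1L, b + 1L] <- as.integer(match)
  m
}

submat_protein <- function(stop_score = -1000L) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  m <- matrix(-4L, 128L, 128L)
  aa <- rownames(B)
  for (i in seq_along(aa)) for (j in seq_along(aa))
    m[utf8ToInt(aa[i]) + 1L, utf8ToInt(aa[j]) + 1L] <- as.integer(B[i, j])
  star <- utf8ToInt("*") + 1L
  m[star, ] <- stop_score
  m[, star] <- stop_score
  m
}

empty_hit_set <- function(query_id) {
  structure(data.frame(
    query_id = character(0), subject = character(0), taxon = character(0),
    raw_score = numeric(0), bit_score = numeric(0), identity_pct = numeric(0),
    align_length = integer(0), qstart = integer(0), qend = integer(0),
    sstart = integer(0), send = integer(0), strand = character(0),
    qaln = character(0), saln = character(0), stringsAsFactors = FALSE),
    query_id = query_id, class = c("hit_set", "data.frame"))
}

aln_identity <- function(qaln, saln) {
  qa <- strsplit(qaln, "")[[1L]]
  sa <- strsplit(saln, "")[[1L]]
  100 * sum(qa == sa & qa != "-") / length(qa)
}

#' Nucleotide search of reads against the reference database
#'
#' For each read, references sharing an exact word of `word_size` nucleotides
#' with either strand are aligned (optimal affine-gap local alignment); the
#' best hit per leaf taxon with `bit_score >= min_report_bits` is kept,
#' sorted by bit score.  A read sharing no word with any reference yields an
#' empty hit set ("no hits").  Identity is identical columns over alignment
#' columns, gaps included.
#'
#' @param reads data.frame of reads (or named character vector).
#' @param db A `reference_db`.
#' @param cfg A [search_config()].
#' @return Named list of `hit_set` data frames, one per read.  Minus-strand
#'   hits report query coordinates on the reverse-complemented read.
#' @export
search_nucleotide <- function(reads, db, cfg = search_config()) {
  reads <- as_read_df(reads)
  sub <- submat_dna(cfg$match_reward, cfg$mismatch_penalty)
  refs <- toupper(db$records$sequence)
  out <- vector("list", nrow(reads))
  names(out) <- reads$read_id
  for (i in seq_len(nrow(reads))) {
    fwd <- toupper(reads$sequence[i])
    rc <- revcomp_cpp(fwd)
    seeds <- seed_strands_cpp(fwd, rc, refs, cfg$word_size)
    rows <- list()
    for (r in which(seeds[, 1L] == 1L | seeds[, 2L] == 1L)) {
      best <- NULL
      for (strand in c("+", "-")[c(seeds[r, 1L] == 1L, seeds[r, 2L] == 1L)]) {
        q <- if (strand == "+") fwd else rc
        al <- sw_align_cpp(q, refs[r], sub, cfg$gap_open, cfg$gap_extend)
        if (is.null(best) || al$score > best$al$score)
          best <- list(al = al, strand = strand)
      }
      al <- best$al
      if (al$score <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = reads$read_id[i], subject = db$records$accession[r],
        taxon = db$records$taxon[r], raw_score = al$score,
        bit_score = bit_score(al$score, cfg$lambda, cfg$k_const),
        identity_pct = aln_identity(al$qaln, al$saln),
        align_length = nchar(al$qaln), qstart = al$qstart, qend = al$qend,
        sstart = al$sstart, send = al$send, strand = best$strand,
        qaln = al$qaln, saln = al$saln, stringsAsFactors = FALSE)
    }
    out[[i]] <- reduce_hit_set(rows, reads$read_id[i], cfg$min_report_bits)
  }
  out
}

reduce_hit_set <- function(rows, query_id, min_bits = 0) {
  if (!length(rows)) return(empty_hit_set(query_id))
  h <- do.call(rbind, rows)
  h <- h[h$bit_score >= min_bits, , drop = FALSE]
  if (!nrow(h)) return(empty_hit_set(query_id))
  h <- h[order(-h$bit_score, h$taxon, h$subject), , drop = FALSE]
  h <- h[!duplicated(h$taxon), , drop = FALSE]
  rownames(h) <- NULL
  structure(h, query_id = query_id, class = c("hit_set", "data.frame"))
}

#' Translate a nucleotide sequence
#'
#' `translate_sequence` translates one frame (1-3 forward, trimmed to whole
#' codons; stops become `*`).  `translate_frames` returns all six frames
#' (three forward, three reverse-complement).
#'
#' @param seq Nucleotide string.
#' @param frame Frame 1-3.
#' @return Amino-acid string(s).
#' @export
translate_sequence <- function(seq, frame = 1) {
  stopifnot(frame >= 1, frame <= 3)
  translate_one_frame(toupper(seq), frame)
}

translate_one_frame <- function(seqs, frame) {
  n <- nchar(seqs)
  w <- pmax(0L, n - frame + 1L)
  w <- w - w %% 3L
  out <- rep("", length(seqs))
  ok <- w >= 3L
  if (any(ok)) {
    x <- Biostrings::subseq(Biostrings::DNAStringSet(seqs[ok]),
                            start = frame, width = w[ok])
    out[ok] <- as.character(Biostrings::translate(x,
                                                  if.fuzzy.codon = "solve"))
  }
  out
}

# all six frames for a vector of sequences: list of 6-vectors
translate_frames_many <- function(seqs) {
  seqs <- toupper(seqs)
  rc <- vapply(seqs, revcomp_cpp, character(1), USE.NAMES = FALSE)
  fr <- c(lapply(1:3, function(f) translate_one_frame(seqs, f)),
          lapply(1:3, function(f) translate_one_frame(rc, f)))
  lapply(seq_along(seqs), function(i)
    vapply(fr, `[`, character(1), i))
}

#' @rdname translate_sequence
#' @export
translate_frames <- function(seq) {
  translate_frames_many(seq)[[1L]]
}

#' Translated (six-frame) search of reads against the reference database
#'
#' All six reading frames of the read are compared with all six frames of
#' each reference, seeding on exact shared words of `tx_word_size` residues
#' and extending without gaps under BLOSUM62 with X-drop termination; stop
#' codons truncate extensions.  Used to rescue highly divergent CuMMO reads
#' whose protein, but not nucleotide, sequence still resembles the database.
#'
#' @inheritParams search_nucleotide
#' @return Named list of `hit_set` data frames (best hit per taxon by
#'   translated bit score; coordinates are 1-based amino-acid positions in
#'   the reported frames, frames 4-6 being reverse-complement frames 1-3).
#' @export
search_translated <- function(reads, db, cfg = search_config()) {
  reads <- as_read_df(reads)
  sub <- submat_protein()
  ref_frames <- translate_frames_many(db$records$sequence)
  read_frames <- translate_frames_many(reads$sequence)
  out <- vector("list", nrow(reads))
  names(out) <- reads$read_id
  for (i in seq_len(nrow(reads))) {
    qf <- read_frames[[i]]
    rows <- list()
    for (r in seq_along(ref_frames)) {
      h <- tx_best_hsp_cpp(qf, ref_frames[[r]], sub, cfg$tx_word_size,
                           cfg$tx_xdrop)
      if (h[1L] <= 0) next
      qseg <- substr(qf[h[2L]], h[4L], h[5L])
      sseg <- substr(ref_frames[[r]][h[3L]], h[6L], h[7L])
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = reads$read_id[i], subject = db$records$accession[r],
        taxon = db$records$taxon[r], raw_score = h[1L],
        bit_score = bit_score(h[1L], cfg$tx_lambda, cfg$tx_k),
        identity_pct = aln_identity(qseg, sseg),
        align_length = nchar(qseg), qstart = as.integer(h[4L]),
        qend = as.integer(h[5L]), sstart = as.integer(h[6L]),
        send = as.integer(h[7L]),
        strand = sprintf("%d/%d", h[2L], h[3L]),
        qaln = qseg, saln = sseg, stringsAsFactors = FALSE)
    }
    out[[i]] <- reduce_hit_set(rows, reads$read_id[i], cfg$min_report_bits)
  }
  out
}

#' Parse externally produced 12-column tabular search output
#'
#' Reads the standard 12-column tab-separated format (query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score), maps subject accessions to taxa
#' through the reference database, and reduces each query to its best hit per
#' taxon.  Rows whose subject accession is unknown are dropped with a
#' message; malformed rows raise an error naming the line.
#'
#' @param x Path to a tabular results file, or a data.frame of 12 columns.
#' @param db A `reference_db` providing the accession-to-taxon mapping.
#' @return Named list of `hit_set` data frames (no alignment strings).
#' @export
parse_external_tabular <- function(x, db) {
  if (is.character(x) && !is.data.frame(x)) {
    lines <- readLines(x)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(list())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 12L)
    if (length(bad))
      stop(sprintf("malformed tabular row at line %d (expected 12 columns)",
                   bad[1L]))
    x <- as.data.frame(do.call(rbind, lapply(parts, `[`, 1:12)),
                       stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (ncol(x) < 12L) stop("expected 12 columns of tabular search output")
  names(x)[1:12] <- c("query_id", "subject", "identity_pct", "align_length",
                      "mismatch", "gapopen", "qstart", "qend", "sstart",
                      "send", "evalue", "bit_score")
  for (col in c("identity_pct", "align_length", "qstart", "qend", "sstart",
                "send", "bit_score")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    if (anyNA(v))
      stop(sprintf("malformed tabular row at line %d (non-numeric %s)",
                   which(is.na(v))[1L], col))
    x[[col]] <- v
  }
  taxon <- db$records$taxon[match(x$subject, db$records$accession)]
  unknown <- is.na(taxon)
  if (any(unknown))
    message(sprintf("parse_external_tabular: dropped %d row(s) with unknown subject",
                    sum(unknown)))
  x <- x[!unknown, , drop = FALSE]
  x$taxon <- taxon[!unknown]
  x$raw_score <- NA_real_
  x$strand <- NA_character_
  x$qaln <- NA_character_
  x$saln <- NA_character_
  keep <- c("query_id", "subject", "taxon", "raw_score", "bit_score",
            "identity_pct", "align_length", "qstart", "qend", "sstart",
            "send", "strand", "qaln", "saln")
  lapply(split(x[keep], factor(x$query_id, levels = unique(x$query_id))),
         function(h) reduce_hit_set(split(h, seq_len(nrow(h))),
                                    h$query_id[1L]))
}

#' Write hit sets in 12-column tabular form plus a taxon column
#'
#' @param hitsets List of `hit_set` objects.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hitsets, path) {
  h <- do.call(rbind, lapply(hitsets, function(x) as.data.frame(x)))
  if (is.null(h) || !nrow(h)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  mism <- round((100 - h$identity_pct) / 100 * h$align_length)
  out <- data.frame(h$query_id, h$subject, sprintf("%.2f", h$identity_pct),
                    h$align_length, mism, 0L, h$qstart, h$qend, h$sstart,
                    h$send, "NA", sprintf("%.1f", h$bit_score), h$taxon)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
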