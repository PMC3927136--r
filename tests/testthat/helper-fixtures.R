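# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

shared_db <- function() {
  if (is.null(.fixtures$db)) .fixtures$db <- mock_reference_db()
  .fixtures$db
}

shared_nbc_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- nbc_train(shared_db())
  .fixtures$model
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, n_sub) {
  chars <- strsplit(seq, "")[[1L]]
  pos <- sample(length(chars), n_sub)
  for (p in pos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

# a tiny flat taxonomy (root + one leaf per name) for aligner tests
flat_db <- function(seqs) {
  names(seqs) <- paste0("T", seq_along(seqs))
  tab <- data.frame(level_code = c("0", paste0("0.", seq_along(seqs))),
                    name = c("root", names(seqs)),
                    stringsAsFactors = FALSE)
  reference_db(data.frame(accession = paste0("ref", seq_along(seqs)),
                          taxon = names(seqs), sequence = unname(seqs),
                          stringsAsFactors = FALSE),
               load_taxonomy_table(tab))
}

# independent Smith-Waterman oracle (Biostrings), same scoring scheme
oracle_sw_score <- function(a, b, match = 1, mismatch = -2, gap_open = 5,
                            gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_ext,
    type = "local"))
}

# does any exact shared word of size w exist (plain R, independent of the
# engine's hashing)?
oracle_has_word <- function(a, b, w) {
  wa <- substring(a, 1:(nchar(a) - w + 1), w:nchar(a))
  wb <- substring(b, 1:(nchar(b) - w + 1), w:nchar(b))
  length(intersect(wa, wb)) > 0
}

# random hit set over the packaged taxonomy for LCA property tests
random_hit_set <- function(tree, n_taxa, query_id = "q") {
  if (n_taxa == 0)
    return(structure(
      data.frame(query_id = character(0), subject = character(0),
                 taxon = character(0), raw_score = numeric(0),
                 bit_score = numeric(0), identity_pct = numeric(0),
                 align_length = integer(0), qstart = integer(0),
                 qend = integer(0), sstart = integer(0), send = integer(0),
                 strand = character(0), qaln = character(0),
                 saln = character(0), stringsAsFactors = FALSE),
      query_id = query_id, class = c("hit_set", "data.frame")))
  leaves <- sample(taxon_leaves(tree), n_taxa)
  h <- data.frame(query_id = query_id, subject = paste0("s", seq_len(n_taxa)),
                  taxon = leaves, raw_score = NA_real_,
                  bit_score = round(stats::runif(n_taxa, 80, 900), 1),
                  identity_pct = NA_real_, align_length = NA_integer_,
                  qstart = NA_integer_, qend = NA_integer_,
                  sstart = NA_integer_, send = NA_integer_,
                  strand = "+", qaln = NA_character_, saln = NA_character_,
                  stringsAsFactors = FALSE)
  h <- h[order(-h$bit_score), , drop = FALSE]
  rownames(h) <- NULL
  structure(h, query_id = query_id, class = c("hit_set", "data.frame"))
}

# hand-built single-hit rows for conserved-mismatch tests
aln_hit <- function(qaln, saln, subject = "R1", sstart = 1L) {
  data.frame(query_id = "q", subject = subject, taxon = "T1",
             raw_score = NA_real_, bit_score = NA_real_,
             identity_pct = NA_real_, align_length = nchar(qaln),
             qstart = 1L, qend = nchar(gsub("-", "", qaln)),
             sstart = sstart,
             send = sstart + nchar(gsub("-", "", saln)) - 1L,
             strand = "+", qaln = qaln, saln = saln,
             stringsAsFactors = FALSE)
}
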