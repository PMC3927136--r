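# Seeded synthetic data: a mock reference database evolved along the
# packaged taxonomy, and an amplicon read generator with ground truth.
# Everything here is synthetic stand-in material for validation; no sequence
# is a real pmoA sequence.

random_coding_seq <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, n_sub, avoid = integer(0)) {
  if (n_sub == 0L) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  ok <- setdiff(seq_along(chars), avoid)
  pos <- sample(ok, min(n_sub, length(ok)))
  for (p in pos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Generate the bundled mock reference database
#'
#' Builds a small synthetic reference database over the full packaged pmoA
#' taxonomy by evolving a random protein-coding root sequence down the tree
#' with substitutions only (so all references are positionally aligned).
#' Per-edge substitution rates shrink with depth, leaving sister leaf taxa
#' roughly 11-12% diverged from one another -- comfortably above the >5%
#' inter-taxon separation the taxonomy is built on -- and major groups far
#' more.  The gp23 leaf gets an extra-long branch, mirroring its role as a
#' divergent taxon represented by a single sequence.  The number of
#' references per leaf scales with the logarithm of the curated database
#' size (1 for singleton taxa such as gp23, up to 4 for the largest taxa);
#' within-taxon replicates sit at ~2% divergence.
#'
#' Real marker genes are not uniformly variable: strongly conserved stretches
#' (primer-binding sites and functional motifs) anchor word-based seeding
#' even between fairly divergent relatives.  The mock database emulates this
#' with three codon-aligned 24-nt blocks that are exempt from substitution on
#' every edge below the major-group level, so members of the same Type share
#' them exactly.  The block positions are recorded in the `conserved` field,
#' and [synth_reads()] protects them from *uniform* read mutation too --
#' but not from synonymous mutation, since that constraint acts on the
#' protein, leaving silent sites free.
#'
#' @param seed Integer seed; the default defines the canonical mock database.
#' @param n_codons Length of every reference in codons (default 166,
#'   i.e. 498 nt).
#' @param replicate_divergence Within-taxon divergence of replicate
#'   references (default 0.02).
#' @return A `reference_db` over [pmoa_taxonomy()] with synthetic accessions
#'   (`SYN_<taxon>_<i>`) and a `conserved` field of block nt positions.
#' @export
mock_reference_db <- function(seed = 101, n_codons = 166,
                              replicate_divergence = 0.02) {
  set.seed(seed)
  tree <- pmoa_taxonomy()
  L <- 3L * n_codons
  # conserved codon blocks 21-28, 81-88, 141-148 (1-based nt positions)
  blocks <- as.integer(c(61:84, 241:264, 421:444))
  edge_rate <- c(0, 0.16, 0.10, 0.08, 0.06)  # indexed by child depth
  seqs <- list()
  seqs[[taxon_root(tree)]] <- random_coding_seq(n_codons)
  walk <- function(name) {
    for (ch in taxon_children(tree, name)) {
      depth <- tree$nodes[ch, "depth"]
      rate <- if (ch == "gp23") 0.25 else edge_rate[depth]
      avoid <- if (depth >= 4L) blocks else integer(0)
      seqs[[ch]] <<- mutate_seq(seqs[[name]], round(rate * L), avoid)
      walk(ch)
    }
  }
  walk(taxon_root(tree))
  leaves <- tree$nodes[tree$nodes$is_leaf, , drop = FALSE]
  recs <- list()
  for (i in seq_len(nrow(leaves))) {
    tx <- leaves$name[i]
    n_ref <- min(4L, 1L + floor(log10(max(1, leaves$db_size[i]))))
    for (r in seq_len(n_ref)) {
      s <- if (r == 1L) seqs[[tx]]
           else mutate_seq(seqs[[tx]], round(replicate_divergence * L),
                           blocks)
      recs[[length(recs) + 1L]] <- data.frame(
        accession = sprintf("SYN_%s_%d", tx, r), taxon = tx, sequence = s,
        stringsAsFactors = FALSE)
    }
  }
  db <- reference_db(do.call(rbind, recs), tree)
  db$conserved <- blocks
  db
}

#' Describe one synthetic read group
#'
#' @param source A leaf taxon name, or an internal node name.  Reads from an
#'   internal source emulate a novel lineage branching at that node: the
#'   template is a balanced midpoint of reference sequences from two
#'   different child subtrees, so reads score similarly against both sides.
#' @param divergence Additional divergence from the template, as a fraction.
#' @param model `"uniform"` (random substitutions) or `"synonymous"`
#'   (substitutions restricted to synonymous third-codon-position changes, so
#'   nucleotide identity drops while the protein is untouched).
#' @param planted Number of shared substitutions planted identically in every
#'   read of the group (conserved-mismatch ground truth), or NA.
#' @return A list of class `synth_group`.
#' @export
synth_group <- function(source, divergence = 0, model = c("uniform",
                                                          "synonymous"),
                        planted = NA_integer_) {
  model <- match.arg(model)
  stopifnot(divergence >= 0, divergence <= 1)
  structure(list(source = source, divergence = divergence, model = model,
                 planted = planted), class = "synth_group")
}

#' The canonical validation groups
#'
#' Three read groups spanning the novelty tiers: near-identical reads from a
#' well-represented leaf (2% divergence), reads from a simulated novel
#' lineage branching at the TypeIIa node (midpoint template plus 8%
#' divergence, the situation that drives LCA assignments to internal nodes),
#' and a deeply divergent group whose substitutions are all synonymous (28%
#' nucleotide divergence with the protein conserved, so only a translated
#' search recognizes it).  Contaminants are added separately via
#' `contaminant_fraction`.
#'
#' @return List of [synth_group()] objects.
#' @export
canonical_groups <- function() {
  list(synth_group("Mcystis", 0.02),
       synth_group("TypeIIa", 0.08),
       synth_group("USCa", 0.28, "synonymous"))
}

syn_mutate <- function(seq, n_target, avoid = integer(0)) {
  gc <- Biostrings::GENETIC_CODE
  chars <- strsplit(seq, "")[[1L]]
  n_codon <- length(chars) %/% 3L
  eligible <- list()
  for (ci in seq_len(n_codon)) {
    p <- 3L * (ci - 1L) + 1L
    if (any(seq(p, p + 2L) %in% avoid)) next
    codon <- paste(chars[p:(p + 2L)], collapse = "")
    aa <- gc[[codon]]
    alts <- names(gc)[gc == aa &
                        substr(names(gc), 1, 2) == substr(codon, 1, 2) &
                        names(gc) != codon]
    if (length(alts)) eligible[[length(eligible) + 1L]] <-
        list(ci = ci, alts = alts)
  }
  if (!length(eligible)) return(list(seq = seq, n_applied = 0L))
  pick <- sample(seq_along(eligible), min(n_target, length(eligible)))
  for (e in eligible[pick]) {
    p <- 3L * (e$ci - 1L) + 1L
    alt <- if (length(e$alts) == 1L) e$alts else sample(e$alts, 1L)
    chars[p:(p + 2L)] <- strsplit(alt, "")[[1L]]
  }
  list(seq = paste(chars, collapse = ""), n_applied = length(pick))
}

group_template <- function(db, source, window = NULL) {
  tree <- db$tree
  if (!taxon_exists(tree, source)) stop(sprintf("unknown source '%s'", source))
  if (taxon_is_leaf(tree, source)) {
    rec <- db$records[db$records$taxon == source, , drop = FALSE]
    if (!nrow(rec)) stop(sprintf("no references for taxon '%s'", source))
    return(list(seq = rec$sequence[1L], label = source))
  }
  ch <- taxon_children(tree, source)
  if (length(ch) < 2L)
    stop(sprintf("internal source '%s' needs at least two children", source))
  pick_ref <- function(node) {
    for (lf in taxon_leaves(tree, node)) {
      rec <- db$records[db$records$taxon == lf, , drop = FALSE]
      if (nrow(rec)) return(rec$sequence[1L])
    }
    stop(sprintf("no references under '%s'", node))
  }
  a <- strsplit(pick_ref(ch[1L]), "")[[1L]]
  b <- strsplit(pick_ref(ch[2L]), "")[[1L]]
  if (length(a) != length(b))
    stop("internal-source templates require equal-length references")
  diff <- which(a != b)
  # balanced midpoint: take half of the differing positions from each parent,
  # balancing separately inside and outside the read window so windowed reads
  # stay equidistant from both child clades
  in_win <- if (is.null(window)) rep(TRUE, length(diff))
            else diff >= window[1L] & diff <= window[1L] + window[2L] - 1L
  take_b <- c(sample(diff[in_win], floor(sum(in_win) / 2)),
              sample(diff[!in_win], floor(sum(!in_win) / 2)))
  a[take_b] <- b[take_b]
  list(seq = paste(a, collapse = ""), label = source)
}

#' Generate synthetic amplicon reads with ground truth
#'
#' Each group emulates one amplicon: a single in-frame window of
#' `read_length` is drawn from the group template (a reference of the source
#' taxon, or a balanced midpoint template for an internal source) and every
#' read of the group is an independently mutated copy of that window at the
#' requested divergence.  Planted shared substitutions are applied
#' identically to every read of the group at fixed window positions (kept
#' away from the window edges so local alignments retain them).  Contaminants are i.i.d. uniform nucleotide strings;
#' chimeras join a prefix and suffix from references of two different taxa at
#' a random breakpoint; homopolymer indels extend or contract an existing
#' run by one base.
#'
#' @param db A `reference_db` (typically [mock_reference_db()]).
#' @param groups List of [synth_group()]s (default [canonical_groups()]).
#' @param n_per_group Reads per group (default 25).
#' @param read_length Read length in bp (default 400).
#' @param contaminant_fraction,chimera_fraction Numbers of contaminant and
#'   chimeric reads as fractions of the grouped reads (defaults 0).
#' @param homopolymer_indel_rate Per-read probability of one homopolymer
#'   indel (default 0).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return list with `reads` (data.frame: read_id, sample, sequence) and
#'   `truth` (data.frame: read_id, group, source, true_taxon, divergence,
#'   realized_divergence, model, expected_tier, window_start,
#'   planted_positions -- read coordinates, comma-joined).
#' @export
synth_reads <- function(db, groups = canonical_groups(), n_per_group = 25,
                        read_length = 400, contaminant_fraction = 0,
                        chimera_fraction = 0, homopolymer_indel_rate = 0,
                        seed = 1L) {
  stopifnot(contaminant_fraction >= 0, contaminant_fraction <= 1,
            chimera_fraction >= 0, chimera_fraction <= 1)
  if (inherits(groups, "synth_group")) groups <- list(groups)
  set.seed(seed)
  ref_len <- unique(nchar(db$records$sequence))
  if (read_length > max(ref_len))
    stop("read_length exceeds the reference length")
  reads <- list(); truth <- list()
  add <- function(id, seqc, group, source, taxon, div, rdiv, model, tier,
                  wstart, planted) {
    reads[[length(reads) + 1L]] <<- data.frame(
      read_id = id, sample = "synthetic", sequence = seqc,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      read_id = id, group = group, source = source, true_taxon = taxon,
      divergence = div, realized_divergence = rdiv, model = model,
      expected_tier = tier, window_start = wstart,
      planted_positions = planted, stringsAsFactors = FALSE)
  }
  in_frame_starts <- seq(1L, max(ref_len) - read_length + 1L, by = 3L)

  for (g in seq_along(groups)) {
    grp <- groups[[g]]
    shared_start <- sample(in_frame_starts, 1L)
    tmpl <- group_template(db, grp$source,
                           window = c(shared_start, read_length))
    label <- sprintf("g%d_%s", g, grp$source)
    is_internal <- !taxon_is_leaf(db$tree, grp$source)
    tier <- if (is_internal) "internal_node_candidate"
            else if (grp$model == "synonymous" && grp$divergence >= 0.2)
              "divergent_CuMMO"
            else "leaf_assigned"
    has_planted <- !is.na(grp$planted) && grp$planted > 0
    planted_pos <- integer(0)
    planted_base <- character(0)
    cons_win <- integer(0)
    if (!is.null(db$conserved)) {
      cw <- db$conserved[db$conserved >= shared_start &
                           db$conserved <= shared_start + read_length - 1L]
      cons_win <- cw - shared_start + 1L
    }
    if (has_planted) {
      # plant in variable positions only: novel clades share the conserved
      # machinery, and interior placement keeps local alignments full length
      planted_pos <- sort(sample(setdiff(21:(read_length - 20L), cons_win),
                                 grp$planted))
      tchars <- strsplit(substr(tmpl$seq, shared_start,
                                shared_start + read_length - 1L), "")[[1L]]
      planted_base <- vapply(planted_pos, function(p)
        sample(setdiff(c("A", "C", "G", "T"), tchars[p]), 1L), character(1))
    }
    for (j in seq_len(n_per_group)) {
      wstart <- shared_start
      w <- substr(tmpl$seq, wstart, wstart + read_length - 1L)
      if (has_planted) {
        chars <- strsplit(w, "")[[1L]]
        chars[planted_pos] <- planted_base
        w <- paste(chars, collapse = "")
      }
      n_mut <- round(grp$divergence * read_length)
      if (grp$model == "synonymous") {
        res <- syn_mutate(w, n_mut, avoid = planted_pos)
        w <- res$seq; applied <- res$n_applied
      } else {
        w <- mutate_seq(w, n_mut, avoid = c(planted_pos, cons_win))
        applied <- n_mut
      }
      add(sprintf("%s_r%03d", label, j), w, label, grp$source,
          if (is_internal) grp$source else grp$source,
          grp$divergence, applied / read_length, grp$model, tier, wstart,
          paste(planted_pos, collapse = ","))
    }
  }

  n_core <- length(groups) * n_per_group
  leaf_taxa <- unique(db$records$taxon)
  n_chim <- round(chimera_fraction * n_core)
  for (j in seq_len(n_chim)) {
    tx <- sample(leaf_taxa, 2L)
    s1 <- db$records$sequence[match(tx[1L], db$records$taxon)]
    s2 <- db$records$sequence[match(tx[2L], db$records$taxon)]
    w1 <- sample(in_frame_starts, 1L); w2 <- sample(in_frame_starts, 1L)
    bp <- sample(150:250, 1L)
    seqc <- paste0(substr(s1, w1, w1 + bp - 1L),
                   substr(s2, w2 + bp, w2 + read_length - 1L))
    add(sprintf("chim_r%03d", j), seqc, "chimera",
        paste(tx, collapse = "+"), "chimera", NA_real_, NA_real_,
        "chimera", NA_character_, NA_integer_, "")
  }
  n_cont <- round(contaminant_fraction * n_core)
  for (j in seq_len(n_cont)) {
    seqc <- paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
                  collapse = "")
    add(sprintf("contam_r%03d", j), seqc, "contaminant", "contaminant",
        "contaminant", NA_real_, NA_real_, "random", "contaminant",
        NA_integer_, "")
  }

  reads <- do.call(rbind, reads)
  truth <- do.call(rbind, truth)
  if (homopolymer_indel_rate > 0) {
    for (i in seq_len(nrow(reads))) {
      if (stats::runif(1) >= homopolymer_indel_rate) next
      r <- rle(strsplit(reads$sequence[i], "")[[1L]])
      runs <- which(r$lengths >= 2L)
      if (!length(runs)) next
      pick <- sample(runs, 1L)
      r$lengths[pick] <- r$lengths[pick] + sample(c(-1L, 1L), 1L)
      reads$sequence[i] <- paste(inverse.rle(r), collapse = "")
    }
  }
  rownames(reads) <- rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}
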