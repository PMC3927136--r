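# Naive Bayesian k-mer classifier with bootstrap confidence (the RDP-style
# "wang" word-matching model, trained on the leaf taxa of a reference_db).
#
# Training uses presence/absence of each k-mer per sequence:
#   prior   P(w)   = (n(w) + 0.5) / (N + 1)   n(w) = training sequences with w
#   cond.   P(w|G) = (m(w) + P(w)) / (M + 1)  m(w) = G's sequences with w,
#                                             M = number of sequences in G
# A read is scored by sum(log P(w|G)) over its distinct k-mers; confidence
# comes from bootstrap resampling of the k-mer set.

#' Classifier configuration
#'
#' @param kmer_size Word size (default 8; 10 reduces spurious attraction of
#'   random sequences to sparsely represented divergent taxa at the cost of
#'   sensitivity).
#' @param bootstrap_iterations Bootstrap draws per read (default 100).
#' @param subsample_fraction Fraction of the read's distinct k-mers drawn,
#'   with replacement, per bootstrap iteration (default 1/8).
#' @param confidence_cutoff Percent bootstrap confidence required to report a
#'   rank (default 80).
#' @return A list of class `nbc_config`.
#' @export
nbc_config <- function(kmer_size = 8, bootstrap_iterations = 100,
                       subsample_fraction = 1 / 8, confidence_cutoff = 80) {
  stopifnot(kmer_size >= 1, kmer_size <= 15, bootstrap_iterations >= 1,
            subsample_fraction > 0, subsample_fraction <= 1,
            confidence_cutoff >= 0, confidence_cutoff <= 100)
  structure(list(kmer_size = as.integer(kmer_size),
                 bootstrap_iterations = as.integer(bootstrap_iterations),
                 subsample_fraction = subsample_fraction,
                 confidence_cutoff = confidence_cutoff),
            class = "nbc_config")
}

#' Train the naive Bayesian k-mer classifier
#'
#' @param db A `reference_db`.
#' @param cfg An [nbc_config()].
#' @return An `nbc_model` holding, for every k-mer observed in training, the
#'   per-taxon sequence counts, together with the word priors, per-taxon
#'   training sizes and the taxonomy.  Leaves without training sequences are
#'   excluded from scoring (with a message).
#' @export
nbc_train <- function(db, cfg = nbc_config()) {
  k <- cfg$kmer_size
  taxa <- sort(unique(db$records$taxon))
  empty <- setdiff(taxon_leaves(db$tree), taxa)
  if (length(empty))
    message(sprintf("nbc_train: %d leaf taxa have no training sequences",
                    length(empty)))
  keys_per_seq <- lapply(db$records$sequence, kmer_keys_cpp, k = k)
  all_keys <- sort(unique(unlist(keys_per_seq)))
  m <- matrix(0L, nrow = length(all_keys), ncol = length(taxa),
              dimnames = list(NULL, taxa))
  for (i in seq_along(keys_per_seq)) {
    g <- match(db$records$taxon[i], taxa)
    idx <- match(keys_per_seq[[i]], all_keys)
    m[idx, g] <- m[idx, g] + 1L
  }
  Mg <- as.integer(table(factor(db$records$taxon, levels = taxa)))
  N <- nrow(db$records)
  prior <- (rowSums(m) + 0.5) / (N + 1)
  structure(list(kmer_size = k, taxa = taxa, keys = all_keys, m = m,
                 Mg = setNames(Mg, taxa), N = N, prior = prior,
                 tree = db$tree),
            class = "nbc_model")
}

#' @export
print.nbc_model <- function(x, ...) {
  cat(sprintf("nbc_model: k=%d, %d taxa, %d training sequences, %d k-mers\n",
              x$kmer_size, length(x$taxa), x$N, length(x$keys)))
  invisible(x)
}

# per-k-mer log P(w|G) contributions for one k-mer key set: |keys| x T matrix
nbc_contrib <- function(model, keys) {
  idx <- match(keys, model$keys)
  Tn <- length(model$taxa)
  C <- matrix(log(0.5 / (model$N + 1)), nrow = length(keys), ncol = Tn)
  seen <- !is.na(idx)
  if (any(seen)) {
    pm <- model$m[idx[seen], , drop = FALSE] + model$prior[idx[seen]]
    C[seen, ] <- log(pm)
  }
  sweep(C, 2L, log(model$Mg + 1), "-")
}

classify_one <- function(model, sequence, cfg) {
  k <- model$kmer_size
  if (nchar(sequence) < k)
    return(list(ok = FALSE, reason = "shorter than k-mer size"))
  keys_f <- kmer_keys_cpp(sequence, k)
  keys_r <- kmer_keys_cpp(revcomp_cpp(toupper(sequence)), k)
  if (length(keys_f) == 0L && length(keys_r) == 0L)
    return(list(ok = FALSE, reason = "no valid k-mers"))
  Cf <- if (length(keys_f)) nbc_contrib(model, keys_f) else NULL
  Cr <- if (length(keys_r)) nbc_contrib(model, keys_r) else NULL
  sf <- if (is.null(Cf)) -Inf else max(colSums(Cf))
  sr <- if (is.null(Cr)) -Inf else max(colSums(Cr))
  if (sf >= sr) { C <- Cf; strand <- "+" } else { C <- Cr; strand <- "-" }
  full <- colSums(C)
  winner <- model$taxa[which.max(full)]  # taxa sorted: ties -> lexicographic

  s <- ceiling(nrow(C) * cfg$subsample_fraction)
  wins <- integer(length(model$taxa))
  for (b in seq_len(cfg$bootstrap_iterations)) {
    rows <- sample.int(nrow(C), s, replace = TRUE)
    sc <- colSums(C[rows, , drop = FALSE])
    w <- which.max(sc)
    wins[w] <- wins[w] + 1L
  }
  leaf_conf <- setNames(100 * wins / cfg$bootstrap_iterations, model$taxa)
  list(ok = TRUE, strand = strand, winner = winner,
       winner_score = max(full), leaf_conf = leaf_conf)
}

#' Classify reads with the naive Bayesian classifier
#'
#' Each read's distinct k-mers are extracted from both orientations and the
#' orientation with the higher best-taxon score is used.  Bootstrap
#' resampling of the k-mer set yields a leaf-level confidence (percent of
#' draws won); the confidence of an internal node is the sum over its
#' descendant leaves, so confidences are non-increasing from root to leaf and
#' the root always carries 100%.  The reported taxon is the deepest node on
#' the consensus path whose confidence meets the cutoff; reads that cannot be
#' resolved below the root are effectively "unclassified" at that rank.
#'
#' @param model An `nbc_model`.
#' @param reads data.frame of reads (or named character vector).
#' @param cfg An [nbc_config()]; `kmer_size` must match the model.
#' @param seed Integer seed for the bootstrap (identical seed, identical
#'   result).
#' @return data.frame with one row per read: `read_id`, `reported_taxon`,
#'   `reported_conf`, `winner_leaf`, `winner_score`, `strand`, `path`
#'   (semicolon-joined `node(conf)` entries), and a list column `confidence`
#'   with the full named per-node confidence vector.
#' @export
nbc_classify <- function(model, reads, cfg = nbc_config(), seed = 1L) {
  stopifnot(inherits(model, "nbc_model"))
  if (cfg$kmer_size != model$kmer_size)
    stop("cfg$kmer_size differs from the trained model")
  reads <- as_read_df(reads)
  set.seed(seed)
  tree <- model$tree
  leaves_under <- lapply(setNames(tree$nodes$name, tree$nodes$name),
                         function(n) intersect(taxon_leaves(tree, n),
                                               model$taxa))
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    res <- classify_one(model, toupper(reads$sequence[i]), cfg)
    if (!res$ok) {
      out[[i]] <- data.frame(read_id = reads$read_id[i],
                             reported_taxon = "unclassified",
                             reported_conf = NA_real_,
                             winner_leaf = NA_character_,
                             winner_score = NA_real_, strand = NA_character_,
                             path = res$reason, stringsAsFactors = FALSE)
      out[[i]]$confidence <- list(NULL)
      next
    }
    conf <- vapply(leaves_under, function(lv)
      if (length(lv)) sum(res$leaf_conf[lv]) else 0, numeric(1))
    # consensus path: descend through the highest-confidence child
    node <- taxon_root(tree); path <- node
    repeat {
      ch <- taxon_children(tree, node)
      if (!length(ch)) break
      node <- ch[order(-conf[ch], ch)][1L]
      path <- c(path, node)
    }
    ok_depth <- which(conf[path] >= cfg$confidence_cutoff)
    reported <- path[max(ok_depth)]
    out[[i]] <- data.frame(
      read_id = reads$read_id[i], reported_taxon = reported,
      reported_conf = unname(conf[reported]),
      winner_leaf = res$winner, winner_score = res$winner_score,
      strand = res$strand,
      path = paste(sprintf("%s(%g)", path, conf[path]), collapse = ";"),
      stringsAsFactors = FALSE)
    out[[i]]$confidence <- list(conf)
  }
  do.call(rbind, out)
}

# ---- flat-file model serialization ----------------------------------------

#' Save or load a trained classifier as a versioned flat text file
#'
#' @param model An `nbc_model`.
#' @param path File path.
#' @return `load_nbc_model` returns the reconstructed `nbc_model`.
#' @export
save_nbc_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#pmoaclass-nbc-model v1",
               sprintf("#kmer_size\t%d", model$kmer_size),
               sprintf("#N\t%d", model$N),
               "#taxa"), con)
  writeLines(sprintf("%s\t%d", model$taxa, model$Mg), con)
  writeLines("#tree", con)
  nd <- model$tree$nodes
  writeLines(sprintf("%s\t%s\t%s", nd$level_code, nd$name,
                     ifelse(is.na(nd$db_size), "", nd$db_size)), con)
  writeLines("#counts", con)
  writeLines(paste(format(model$keys, scientific = FALSE, trim = TRUE),
                   apply(model$m, 1L, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(path)
}

#' @rdname save_nbc_model
#' @export
load_nbc_model <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "#pmoaclass-nbc-model v1")
    stop("not a pmoaclass nbc model file (or unsupported version)")
  k <- as.integer(strsplit(lines[2L], "\t")[[1L]][2L])
  N <- as.integer(strsplit(lines[3L], "\t")[[1L]][2L])
  sec <- function(tag) which(lines == tag)
  i_taxa <- sec("#taxa"); i_tree <- sec("#tree"); i_counts <- sec("#counts")
  taxa_rows <- strsplit(lines[(i_taxa + 1L):(i_tree - 1L)], "\t")
  taxa <- vapply(taxa_rows, `[`, character(1), 1L)
  Mg <- setNames(as.integer(vapply(taxa_rows, `[`, character(1), 2L)), taxa)
  tree_rows <- strsplit(lines[(i_tree + 1L):(i_counts - 1L)], "\t")
  tree <- load_taxonomy_table(data.frame(
    level_code = vapply(tree_rows, `[`, character(1), 1L),
    name = vapply(tree_rows, `[`, character(1), 2L),
    db_size = vapply(tree_rows, function(r)
      if (length(r) >= 3L) r[3L] else "", character(1)),
    stringsAsFactors = FALSE))
  cm <- do.call(rbind, strsplit(lines[(i_counts + 1L):length(lines)], "\t"))
  keys <- as.numeric(cm[, 1L])
  m <- matrix(as.integer(cm[, -1L, drop = FALSE]), nrow = nrow(cm),
              dimnames = list(NULL, taxa))
  structure(list(kmer_size = k, taxa = taxa, keys = keys, m = m, Mg = Mg,
                 N = N, prior = (rowSums(m) + 0.5) / (N + 1), tree = tree),
            class = "nbc_model")
}
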