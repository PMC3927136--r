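# Naive Bayesian k-mer classifier: training formulas, scoring oracle,
# bootstrap confidence.

tiny_tree <- function(n_leaves) {
  load_taxonomy_table(data.frame(
    level_code = c("0", paste0("0.", seq_len(n_leaves))),
    name = c("root", paste0("T", seq_len(n_leaves)))))
}

test_that("word priors and conditionals follow the pseudocount formulas", {
  db <- reference_db(data.frame(accession = "a1", taxon = "T1",
                                sequence = "ACGTT"), tiny_tree(1))
  cfg <- nbc_config(kmer_size = 4, bootstrap_iterations = 10)
  m <- nbc_train(db, cfg)
  # N = 1; every observed word sits in the one sequence: P(w) = 1.5/2
  expect_true(all(m$prior == 1.5 / 2))
  # conditional for an observed word: (1 + 0.75) / (1 + 1)
  C <- pmoaclass:::nbc_contrib(m, m$keys)
  expect_equal(unique(as.vector(C)), log((1 + 0.75) / 2))
  # a word absent everywhere still gets a positive floor: P(w)/(M+1)
  absent <- setdiff(0:255, m$keys)[1]
  C0 <- pmoaclass:::nbc_contrib(m, absent)
  expect_equal(as.vector(C0), log((0.5 / 2) / 2))
  expect_true(is.finite(C0) && C0 < 0)
})

test_that("identical single-sequence taxa get identical conditionals", {
  s <- random_dna(60)
  db <- reference_db(data.frame(accession = c("a1", "a2"),
                                taxon = c("T1", "T2"),
                                sequence = c(s, s)), tiny_tree(2))
  m <- nbc_train(db, nbc_config(kmer_size = 4))
  expect_identical(m$m[, "T1"], m$m[, "T2"])
})

test_that("full scores match an independent first-principles oracle", {
  # oracle: count word presence with plain substring operations and apply
  # the pseudocount formulas directly
  oracle_scores <- function(records, read, k) {
    km <- function(s) unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
    seq_km <- lapply(records$sequence, km)
    taxa <- sort(unique(records$taxon))
    N <- nrow(records)
    V <- km(read)
    vapply(taxa, function(g) {
      idx <- which(records$taxon == g)
      M <- length(idx)
      sum(vapply(V, function(w) {
        n_w <- sum(vapply(seq_km, function(s) w %in% s, logical(1)))
        m_w <- sum(vapply(seq_km[idx], function(s) w %in% s, logical(1)))
        log((m_w + (n_w + 0.5) / (N + 1)) / (M + 1))
      }, numeric(1)))
    }, numeric(1))
  }
  set.seed(31)
  for (rep in 1:5) {
    records <- data.frame(
      accession = paste0("a", 1:6),
      taxon = rep(c("T1", "T2", "T3"), each = 2),
      sequence = replicate(6, random_dna(60)), stringsAsFactors = FALSE)
    db <- reference_db(records, tiny_tree(3))
    cfg <- nbc_config(kmer_size = 4, bootstrap_iterations = 5)
    model <- nbc_train(db, cfg)
    read <- mutate_dna(substr(records$sequence[1], 1, 50), 3)
    res <- nbc_classify(model, c(q = read), cfg, seed = rep)
    fwd <- oracle_scores(records, read, 4)
    rev <- oracle_scores(records, pmoaclass:::revcomp_cpp(read), 4)
    best <- pmax(max(fwd), max(rev))
    expect_equal(res$winner_score, best, tolerance = 1e-9)
    oracle_winner <- if (max(fwd) >= max(rev)) names(which.max(fwd))
                     else names(which.max(rev))
    expect_identical(res$winner_leaf, oracle_winner)
  }
})

test_that("references classify to their own leaf at full confidence", {
  model <- shared_nbc_model()
  db <- shared_db()
  picks <- db$records[match(c("Mcystis", "JRC_3", "USCa", "AOB_like"),
                            db$records$taxon), ]
  res <- nbc_classify(model, setNames(substr(picks$sequence, 1, 400),
                                      picks$accession), seed = 3)
  expect_identical(res$reported_taxon, picks$taxon)
  expect_true(all(res$reported_conf == 100))
})

test_that("a near-identical read is confidently assigned to its taxon", {
  # two-taxon toy model: read = T1's sequence with one substitution
  set.seed(5)
  s1 <- random_dna(120); s2 <- random_dna(120)
  db <- reference_db(data.frame(accession = c("a1", "a2"),
                                taxon = c("T1", "T2"),
                                sequence = c(s1, s2)), tiny_tree(2))
  cfg <- nbc_config(kmer_size = 6)
  model <- nbc_train(db, cfg)
  res <- nbc_classify(model, c(q = mutate_dna(s1, 1)), cfg, seed = 8)
  expect_identical(res$reported_taxon, "T1")
  expect_gte(res$reported_conf, 80)
})

test_that("confidence mass is conserved and non-increasing along the path", {
  model <- shared_nbc_model()
  set.seed(12)
  reads <- setNames(c(substr(shared_db()$records$sequence[5], 30, 429),
                      random_dna(400)), c("clean", "noise"))
  res <- nbc_classify(model, reads, seed = 4)
  for (i in 1:2) {
    conf <- res$confidence[[i]]
    expect_equal(unname(conf["CuMMO"]), 100)
    path <- strsplit(res$path[i], ";")[[1]]
    nodes <- sub("\\(.*", "", path)
    expect_true(all(diff(conf[nodes]) <= 1e-9))
  }
})

test_that("classification is deterministic under a fixed seed", {
  model <- shared_nbc_model()
  set.seed(77)
  reads <- setNames(replicate(3, random_dna(400)), paste0("r", 1:3))
  a <- nbc_classify(model, reads, seed = 9)
  b <- nbc_classify(model, reads, seed = 9)
  expect_identical(a, b)
})

test_that("reads shorter than k are unclassified with a reason", {
  model <- shared_nbc_model()
  res <- nbc_classify(model, c(tiny = "ACGT"), seed = 1)
  expect_identical(res$reported_taxon, "unclassified")
})

test_that("model flat files round-trip", {
  set.seed(41)
  db <- reference_db(data.frame(accession = paste0("a", 1:4),
                                taxon = c("T1", "T1", "T2", "T3"),
                                sequence = replicate(4, random_dna(80))),
                     tiny_tree(3))
  cfg <- nbc_config(kmer_size = 5)
  model <- nbc_train(db, cfg)
  path <- tempfile(fileext = ".nbc")
  save_nbc_model(model, path)
  back <- load_nbc_model(path)
  expect_identical(back$kmer_size, model$kmer_size)
  expect_identical(back$taxa, model$taxa)
  expect_equal(back$keys, model$keys)
  expect_identical(unname(back$m), unname(model$m))
  read <- mutate_dna(db$records$sequence[1], 2)
  expect_identical(nbc_classify(model, c(q = read), cfg, seed = 2),
                   nbc_classify(back, c(q = read), cfg, seed = 2))
  expect_error(load_nbc_model(system.file("extdata", "pmoa_taxonomy.tsv",
                                          package = "pmoaclass")),
               "not a pmoaclass nbc model")
})
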