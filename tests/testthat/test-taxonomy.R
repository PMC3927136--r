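# Taxonomy representation, validation, import and export.

test_that("packaged taxonomy has the curated structure", {
  tr <- pmoa_taxonomy()
  expect_s3_class(tr, "taxonomy_tree")
  expect_identical(sum(tr$nodes$is_leaf), 54L)
  expect_length(taxon_leaves(tr, "MOB_like"), 53L)
  expect_identical(taxon_leaves(tr, "AOB_like"), "AOB_like")
  expect_identical(taxon_path(tr, "Msarcina"),
                   c("CuMMO", "MOB_like", "TypeI", "TypeIa", "Msarcina"))
  expect_equal(validate_db_sizes(tr), 6628)
  expect_equal(tr$stated_total, 6628)
})

test_that("degenerate tables load as forced by their level codes", {
  one <- load_taxonomy_table(data.frame(level_code = "0", name = "CuMMO"))
  expect_identical(nrow(one$nodes), 1L)
  expect_length(taxon_children(one, "CuMMO"), 0L)

  nested <- load_taxonomy_table(data.frame(
    level_code = c("0", "0.1", "0.1.1", "0.1.2"),
    name = c("r", "a", "b", "c")))
  expect_identical(taxon_children(nested, "r"), "a")
  expect_setequal(taxon_children(nested, "a"), c("b", "c"))
  expect_setequal(taxon_leaves(nested), c("b", "c"))
})

test_that("invalid tables are rejected with informative errors", {
  expect_error(load_taxonomy_table(data.frame(
    level_code = c("0", "0.1", "0.2"), name = c("r", "x", "x"))),
    "duplicate taxon name 'x'.*0\\.1.*0\\.2")
  expect_error(load_taxonomy_table(data.frame(
    level_code = c("0", "0.1.1"), name = c("r", "a"))),
    "orphan level code '0\\.1\\.1'")
  expect_error(load_taxonomy_table(data.frame(
    level_code = c("0", "0.1"), name = c("r", "a"),
    db_size = c("", "-3"))), "negative db_size")
  expect_error(load_taxonomy_table(data.frame(
    level_code = c("0", "0.1"), name = c("r", "r2"),
    db_size = c("", ""))), NA)
})

test_that("db sizes sum over leaves and mismatches are reported", {
  two <- load_taxonomy_table(data.frame(
    level_code = c("0", "0.1", "0.2"), name = c("r", "a", "b"),
    db_size = c("", "3", "4")))
  expect_equal(validate_db_sizes(two), 7)

  # perturb one leaf of the packaged table: the sum moves off the stated
  # total and the consistency report names the culprit
  tab <- read.delim(system.file("extdata", "pmoa_taxonomy.tsv",
                                package = "pmoaclass"),
                    colClasses = "character")
  tab$db_size[tab$name == "JRC_3"] <-
    as.character(as.numeric(tab$db_size[tab$name == "JRC_3"]) + 1)
  perturbed <- load_taxonomy_table(tab)
  expect_warning(
    total <- validate_db_sizes(perturbed, reference = pmoa_taxonomy()),
    class = "pmoaclass_size_mismatch")
  expect_equal(total, 6629)
  w <- tryCatch(validate_db_sizes(perturbed, reference = pmoa_taxonomy()),
                warning = function(w) conditionMessage(w))
  expect_match(w, "JRC_3")
})

test_that("validate_db_sizes is invariant under child reordering", {
  tab <- read.delim(system.file("extdata", "pmoa_taxonomy.tsv",
                                package = "pmoaclass"),
                    colClasses = "character")
  set.seed(1)
  shuffled <- tab[c(1L, sample(2:nrow(tab))), ]  # keep the root row first
  expect_equal(validate_db_sizes(load_taxonomy_table(shuffled)), 6628)
})

test_that("Newick + map export follows the preorder-id dialect", {
  tr <- load_taxonomy_table(data.frame(level_code = c("0", "0.1", "0.2"),
                                       name = c("root", "A", "B")))
  tre <- tempfile(fileext = ".tre"); map <- tempfile(fileext = ".map")
  out <- write_tree_and_map(tr, tre, map)
  expect_identical(out$newick, "(1,2)0;")
  expect_identical(readLines(tre), "(1,2)0;")
  expect_identical(readLines(map), c("0\troot", "1\tA", "2\tB"))

  single <- load_taxonomy_table(data.frame(level_code = "0", name = "root"))
  write_tree_and_map(single, tre, map)
  expect_identical(readLines(tre), "0;")
  expect_identical(readLines(map), "0\troot")
  expect_true(trees_isomorphic(single, read_tree_and_map(tre, map)))
})

test_that("tree/map round-trip is isomorphic, including random trees", {
  tre <- tempfile(fileext = ".tre"); map <- tempfile(fileext = ".map")
  tr <- pmoa_taxonomy()
  write_tree_and_map(tr, tre, map)
  expect_true(trees_isomorphic(tr, read_tree_and_map(tre, map)))

  set.seed(42)
  for (rep in 1:8) {
    rows <- data.frame(level_code = "0", name = "n0",
                       stringsAsFactors = FALSE)
    grow <- function(code, name, depth) {
      if (depth >= 4) return()
      for (i in seq_len(sample(0:3, 1))) {
        child_code <- paste0(code, ".", i)
        child_name <- paste0(name, "_", i)
        rows <<- rbind(rows, data.frame(level_code = child_code,
                                        name = child_name))
        grow(child_code, child_name, depth + 1)
      }
    }
    grow("0", "n0", 1)
    rnd <- load_taxonomy_table(rows)
    write_tree_and_map(rnd, tre, map)
    expect_true(trees_isomorphic(rnd, read_tree_and_map(tre, map)))
  }
})

test_that("mothur-style files carry semicolon paths and round-trip", {
  tr <- pmoa_taxonomy()
  db <- reference_db(data.frame(accession = c("X", "Y"),
                                taxon = c("Msarcina", "AOB_like"),
                                sequence = c("ACGTACGT", "TTGGCCAA")), tr)
  fa <- tempfile(fileext = ".fasta"); tx <- tempfile(fileext = ".tax")
  write_mothur_style_files(db, fa, tx)
  lines <- readLines(tx)
  expect_identical(lines[1L], "X\tCuMMO;MOB_like;TypeI;TypeIa;Msarcina;")
  back <- read_mothur_taxonomy(tx)
  expect_identical(back$leaf, db$records$taxon)
  seqs <- read_fasta_df(fa)
  expect_identical(seqs$read_id, db$records$accession)
  expect_identical(seqs$sequence, db$records$sequence)

  empty <- reference_db(data.frame(accession = character(0),
                                   taxon = character(0),
                                   sequence = character(0)), tr)
  write_mothur_style_files(empty, fa, tx)
  expect_length(readLines(fa), 0L)
  expect_identical(nrow(read_mothur_taxonomy(tx)), 0L)
})

test_that("reference records must resolve to leaves", {
  tr <- pmoa_taxonomy()
  expect_error(reference_db(data.frame(accession = "X", taxon = "TypeIa",
                                       sequence = "ACGT"), tr),
               "not leaves")
  expect_error(reference_db(data.frame(accession = "X", taxon = "NoSuch",
                                       sequence = "ACGT"), tr),
               "not in tree")
})

test_that("reference FASTA headers use the accession [Taxon] dialect", {
  tr <- pmoa_taxonomy()
  db <- reference_db(data.frame(accession = "AB1", taxon = "JRC_3",
                                sequence = "ACGTACGTAA"), tr)
  fa <- tempfile(fileext = ".fasta")
  write_reference_fasta(db, fa)
  expect_identical(readLines(fa)[1L], ">AB1 [JRC_3]")
  back <- read_reference_fasta(fa, tr)
  expect_identical(back$records, db$records)
})
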