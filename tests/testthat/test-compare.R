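# Count tables, subsampling, ecological distances.

asg_df <- function(nodes) {
  data.frame(read_id = paste0("r", seq_along(nodes)), node = nodes,
             stringsAsFactors = FALSE)
}

test_that("count tables are samples x detected nodes", {
  tr <- pmoa_taxonomy()
  tab <- build_count_table(list(s1 = asg_df(c("Mbacter", "Mbacter", "USCa")),
                                s2 = asg_df(c("JRC_3", NA))), tr)
  expect_identical(rownames(tab), c("s1", "s2"))
  expect_setequal(colnames(tab), c("Mbacter", "USCa", "JRC_3"))
  expect_identical(unname(tab["s1", c("Mbacter", "USCa", "JRC_3")]),
                   c(2L, 1L, 0L))
  expect_identical(sum(tab["s2", ]), 1L)  # NA assignment not counted

  expect_error(build_count_table(
    setNames(list(asg_df("USCa"), asg_df("USCa")), c("s1", "s1")), tr),
    "duplicate sample")
})

test_that("dropping internal nodes removes columns and shrinks row sums", {
  tr <- pmoa_taxonomy()
  a <- list(s1 = asg_df(c("Mbacter", "TypeII", "TypeII", "USCa")))
  with_int <- build_count_table(a, tr, include_internal = TRUE)
  no_int <- build_count_table(a, tr, include_internal = FALSE)
  expect_true("TypeII" %in% colnames(with_int))
  expect_false("TypeII" %in% colnames(no_int))
  expect_identical(sum(with_int), 4L)
  expect_identical(sum(no_int), 2L)
})

test_that("count tables agree with per-node summaries for a single sample", {
  tr <- pmoa_taxonomy()
  set.seed(19)
  hitsets <- lapply(1:20, function(i) random_hit_set(tr, sample(1:5, 1),
                                                     paste0("r", i)))
  names(hitsets) <- paste0("r", 1:20)
  asg <- assign_lca_all(hitsets, tr)
  tab <- build_count_table(list(only = asg), tr)
  s <- summarize_assignments(asg, tr)
  expect_identical(unname(tab["only", s$node]), s$count)
  expect_identical(sum(tab), sum(s$count))
})

test_that("subsampling hits the target depth exactly and reproducibly", {
  x <- matrix(c(30L, 10L, 5L, 0L, 8L, 22L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  sub <- subsample_counts(x, 20, seed = 3)
  expect_identical(unname(rowSums(sub)), c(20, 20))
  expect_true(all(sub <= x))
  expect_identical(sub, subsample_counts(x, 20, seed = 3))
  expect_identical(subsample_counts(x, 0, seed = 1), x * 0L)
  # full depth returns each row unchanged
  expect_identical(subsample_counts(x[1, , drop = FALSE], 45, seed = 5),
                   x[1, , drop = FALSE])
  expect_error(subsample_counts(x, 31), "s2")
})

test_that("subsampled counts match the hypergeometric expectation", {
  x <- matrix(c(60L, 30L, 10L), nrow = 1,
              dimnames = list("s", c("A", "B", "C")))
  set.seed(8)
  draws <- replicate(1000, subsample_counts(x, 25)["s", "A"])
  expectation <- 25 * 60 / 100
  se <- sqrt(25 * 0.6 * 0.4 * (100 - 25) / (100 - 1)) / sqrt(1000)
  expect_lt(abs(mean(draws) - expectation), 3 * se)
})

test_that("distances match independent textbook implementations", {
  set.seed(27)
  x <- matrix(rpois(40, 12), nrow = 5,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:8)))
  # textbook re-implementations, written against the formulas directly
  ref <- list(
    euclidean = function(a, b) sqrt(sum((a - b)^2)),
    bray_curtis = function(a, b) sum(abs(a - b)) / sum(a + b),
    hellinger = function(a, b) {
      pa <- a / sum(a); pb <- b / sum(b)
      sqrt(sum((sqrt(pa) - sqrt(pb))^2))
    },
    chi_square = function(a, b) {
      col_mass <- colSums(x) / sum(x)
      sqrt(sum((a / sum(a) - b / sum(b))^2 / col_mass))
    },
    kulczynski = function(a, b)
      1 - 0.5 * (sum(pmin(a, b)) / sum(a) + sum(pmin(a, b)) / sum(b)))
  for (m in names(ref)) {
    d <- community_distance(x, m)
    for (i in 1:5) for (j in 1:5)
      expect_equal(d[i, j], ref[[m]](x[i, ], x[j, ]), tolerance = 1e-12,
                   label = sprintf("%s[%d,%d]", m, i, j))
  }
  # vegan as a second, external cross-check where it offers the same measure
  expect_equal(as.vector(as.dist(community_distance(x, "bray_curtis"))),
               as.vector(vegan::vegdist(x, "bray")), tolerance = 1e-12)
  expect_equal(as.vector(as.dist(community_distance(x, "kulczynski"))),
               as.vector(vegan::vegdist(x, "kulczynski")), tolerance = 1e-12)
  expect_equal(as.vector(as.dist(community_distance(x, "euclidean"))),
               as.vector(stats::dist(x)), tolerance = 1e-12)
})

test_that("distance edge cases and ranges behave", {
  x <- matrix(c(5L, 3L, 2L, 5L, 3L, 2L), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  for (m in c("euclidean", "bray_curtis", "hellinger", "chi_square",
              "kulczynski"))
    expect_equal(unname(community_distance(x, m)["a", "b"]), 0)

  disj <- matrix(c(1L, 0L, 0L, 1L), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_equal(unname(community_distance(disj, "bray_curtis")["a", "b"]), 1)
  expect_equal(unname(community_distance(disj, "kulczynski")["a", "b"]), 1)
  expect_equal(unname(community_distance(disj, "hellinger")["a", "b"]),
               sqrt(2))

  set.seed(33)
  y <- matrix(rpois(30, 6), nrow = 5)
  rownames(y) <- paste0("s", 1:5)
  for (m in c("bray_curtis", "kulczynski")) {
    d <- community_distance(y, m)
    expect_true(all(d >= 0 & d <= 1))
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0))
  }
  expect_true(all(community_distance(y, "hellinger") <= sqrt(2) + 1e-12))

  expect_error(community_distance(y, "goodall"), "arg")
  z <- y; z[2, ] <- 0L
  expect_error(community_distance(z, "bray_curtis"), "all-zero")
  expect_error(community_distance(z, "euclidean"), NA)
})
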