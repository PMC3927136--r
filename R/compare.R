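# Cross-sample summaries: count tables, subsampling, ecological distances.

#' Build a samples-by-nodes count table
#'
#' One row per sample, one column per node with at least one read assigned in
#' at least one sample.  Internal-node assignments can be dropped, in which
#' case those columns disappear and row sums shrink accordingly.
#'
#' @param assignments Named list of assignment data frames (one per sample,
#'   from [assign_lca_all()]); names are the sample labels.
#' @param tree A `taxonomy_tree`.
#' @param include_internal Keep assignments at internal nodes (default TRUE).
#' @return Integer matrix (samples x nodes).
#' @export
build_count_table <- function(assignments, tree, include_internal = TRUE) {
  if (is.null(names(assignments)) || any(!nzchar(names(assignments))))
    stop("assignments must be a named list (sample labels)")
  if (anyDuplicated(names(assignments)))
    stop(sprintf("duplicate sample label: %s",
                 names(assignments)[duplicated(names(assignments))][1L]))
  counts <- lapply(assignments, function(a) {
    nodes <- a$node[!is.na(a$node)]
    if (!include_internal)
      nodes <- nodes[vapply(nodes, taxon_is_leaf, logical(1), tree = tree)]
    table(nodes)
  })
  all_nodes <- sort(unique(unlist(lapply(counts, names))))
  out <- matrix(0L, nrow = length(assignments), ncol = length(all_nodes),
                dimnames = list(names(assignments), all_nodes))
  for (s in names(assignments))
    out[s, names(counts[[s]])] <- as.integer(counts[[s]])
  out
}

#' Rarefy a count table to even depth
#'
#' Each row is replaced by a uniform draw without replacement of `depth`
#' reads from its multiset of assigned reads, so all row sums equal `depth`.
#'
#' @param x Count matrix (samples x nodes).
#' @param depth Target depth; must not exceed any row sum.
#' @param seed Optional integer seed (fixed seed, identical draw).
#' @return Integer matrix of the same shape.
#' @export
subsample_counts <- function(x, depth, seed = NULL) {
  stopifnot(is.matrix(x), depth >= 0)
  low <- rowSums(x) < depth
  if (any(low))
    stop(sprintf("subsampling depth %d exceeds reads in sample(s): %s",
                 depth, paste(rownames(x)[low], collapse = ", ")))
  if (!is.null(seed)) set.seed(seed)
  out <- x
  out[] <- 0L
  for (s in seq_len(nrow(x))) {
    pool <- rep(colnames(x), x[s, ])
    drawn <- table(sample(pool, depth, replace = FALSE))
    out[s, names(drawn)] <- as.integer(drawn)
  }
  out
}

#' Ecological distance matrices between samples
#'
#' Standard formulas on the rows of a count table:
#' * `euclidean`: on raw counts.
#' * `bray_curtis`: `sum |x - y| / sum (x + y)` (semi-metric, in `[0, 1]`;
#'   1 for disjoint profiles).
#' * `hellinger`: Euclidean distance between square roots of relative
#'   abundances (in `[0, sqrt(2)]`).
#' * `chi_square`: weighted Euclidean distance between relative-abundance
#'   profiles with inverse column-mass weights (the correspondence-analysis
#'   chi-square distance).
#' * `kulczynski`: `1 - (sum min(x,y)/sum x + sum min(x,y)/sum y) / 2`,
#'   i.e. one minus the Kulczynski similarity, in `[0, 1]`.
#'
#' @param x Count matrix (samples x nodes), nonnegative.
#' @param measure One of `"euclidean"`, `"bray_curtis"`, `"hellinger"`,
#'   `"chi_square"`, `"kulczynski"`.
#' @return Symmetric matrix with zero diagonal and attribute `measure`.
#' @export
community_distance <- function(x, measure = c("euclidean", "bray_curtis",
                                              "hellinger", "chi_square",
                                              "kulczynski")) {
  measure <- match.arg(measure)
  stopifnot(is.matrix(x), all(x >= 0))
  n <- nrow(x)
  if (measure != "euclidean" && any(rowSums(x) == 0))
    stop(sprintf("all-zero row(s) for relative measure '%s': %s", measure,
                 paste(rownames(x)[rowSums(x) == 0], collapse = ", ")))
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  pair <- switch(measure,
    euclidean = function(a, b) sqrt(sum((a - b)^2)),
    bray_curtis = function(a, b) sum(abs(a - b)) / sum(a + b),
    hellinger = function(a, b)
      sqrt(sum((sqrt(a / sum(a)) - sqrt(b / sum(b)))^2)),
    kulczynski = function(a, b)
      1 - 0.5 * (sum(pmin(a, b)) / sum(a) + sum(pmin(a, b)) / sum(b)),
    chi_square = local({
      cm <- colSums(x) / sum(x)
      function(a, b) {
        keep <- cm > 0
        sqrt(sum((a[keep] / sum(a) - b[keep] / sum(b))^2 / cm[keep]))
      }
    }))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
    d[i, j] <- d[j, i] <- pair(x[i, ], x[j, ])
  attr(d, "measure") <- measure
  d
}
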