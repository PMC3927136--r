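# Lowest-common-ancestor assignment from best-per-taxon hit sets.

#' LCA configuration
#'
#' @param top_percent Margin: taxa whose bit score is at least
#'   `(1 - top_percent/100)` times the best bit score are retained before
#'   taking their LCA (default 5).
#' @param min_bit_score Hits below this floor are ignored for assignment
#'   (default 0; novelty thresholds live in [novelty_config()]).
#' @return A list of class `lca_config`.
#' @export
lca_config <- function(top_percent = 5, min_bit_score = 0) {
  stopifnot(top_percent >= 0, top_percent <= 100)
  structure(list(top_percent = top_percent, min_bit_score = min_bit_score),
            class = "lca_config")
}

#' Assign a read to the lowest taxonomy node consistent with its near-best hits
#'
#' Retains every taxon whose bit score is within the `top_percent` margin of
#' the best hit (and above `min_bit_score`); the read is assigned to the
#' single retained leaf, or to the lowest common ancestor of the retained
#' taxa.  Larger margins therefore move assignments toward the root, never
#' away from it.  A read with no hits gets node `NA` with status `"no_hit"`;
#' one whose hits all fall below the floor gets `NA` with status
#' `"low_score"`.
#'
#' @param hits A `hit_set` (best hit per taxon).
#' @param tree A `taxonomy_tree` containing every hit taxon.
#' @param cfg An [lca_config()].
#' @return A list of class `assignment`: `read_id`, `node` (name or NA),
#'   `method = "lca"`, `retained` taxa, `best_bits`, `is_internal`, `status`.
#' @export
assign_lca <- function(hits, tree, cfg = lca_config()) {
  read_id <- attr(hits, "query_id")
  if (is.null(read_id)) read_id <- hits$query_id[1L]
  mk <- function(node, retained, best, status) {
    structure(list(read_id = read_id, node = node, method = "lca",
                   retained = retained, best_bits = best,
                   is_internal = !is.na(node) && !taxon_is_leaf(tree, node),
                   status = status), class = "assignment")
  }
  if (!nrow(hits)) return(mk(NA_character_, character(0), NA_real_, "no_hit"))
  unknown <- setdiff(hits$taxon, tree$nodes$name)
  if (length(unknown))
    stop(sprintf("hit taxon not in tree: %s", paste(unknown, collapse = ", ")))
  best <- max(hits$bit_score)
  keep <- hits$bit_score >= (1 - cfg$top_percent / 100) * best &
    hits$bit_score >= cfg$min_bit_score
  retained <- hits$taxon[keep]
  if (!length(retained)) return(mk(NA_character_, character(0), best,
                                   "low_score"))
  node <- if (length(retained) == 1L) retained else taxon_lca(tree, retained)
  mk(node, retained, best, "assigned")
}

#' Assign many reads and tabulate
#'
#' @param hitsets Named list of `hit_set` objects (one per read).
#' @param tree A `taxonomy_tree`.
#' @param cfg An [lca_config()].
#' @return data.frame with one row per read: `read_id`, `node`, `depth`,
#'   `is_internal`, `best_bits`, `status`, `retained` (comma-joined).
#' @export
assign_lca_all <- function(hitsets, tree, cfg = lca_config()) {
  rows <- lapply(hitsets, function(h) {
    a <- assign_lca(h, tree, cfg)
    data.frame(read_id = a$read_id, node = a$node,
               depth = if (is.na(a$node)) NA_integer_
                       else tree$nodes[a$node, "depth"],
               is_internal = a$is_internal, best_bits = a$best_bits,
               status = a$status,
               retained = paste(a$retained, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-node read counts from assignments
#'
#' Counts reads assigned exactly at each node (internal nodes included);
#' counts plus unassigned reads conserve the input size.
#'
#' @param assignments data.frame from [assign_lca_all()].
#' @param tree A `taxonomy_tree`.
#' @return data.frame (`node`, `count`, `depth`, `is_leaf`) with attribute
#'   `unassigned` (number of reads with no node).
#' @export
summarize_assignments <- function(assignments, tree) {
  assigned <- assignments$node[!is.na(assignments$node)]
  tab <- table(assigned)
  out <- data.frame(node = as.character(if (length(tab)) names(tab)
                                        else character(0)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out$depth <- tree$nodes[out$node, "depth"]
  out$is_leaf <- tree$nodes[out$node, "is_leaf"]
  out <- out[order(-out$count, out$node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unassigned") <- sum(is.na(assignments$node))
  out
}
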