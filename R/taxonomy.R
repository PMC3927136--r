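#' @useDynLib pmoaclass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head tail data
NULL

# ---- taxonomy tree ---------------------------------------------------------

new_taxonomy_tree <- function(nodes, stated_total = NA_real_) {
  rownames(nodes) <- nodes$name
  structure(list(nodes = nodes, stated_total = stated_total),
            class = "taxonomy_tree")
}

#' Load a hierarchical taxonomy from a tabular description
#'
#' The table encodes a rooted taxonomy through dotted level codes
#' (`0`, `0.1`, `0.1.1`, ...): each row's parent is the row whose code drops
#' the final dotted component.  Leaf rows may carry a reference-database size,
#' a representative accession and a habitat note.  A `db_size` on the root row
#' is interpreted as the stated total number of reference sequences and kept
#' for consistency checking by [validate_db_sizes()].
#'
#' @param x Path to a tab-delimited file with columns `level_code`, `name`
#'   and optionally `cultivated`, `db_size`, `accession`, `habitat`; or a
#'   `data.frame` with those columns.
#' @return A `taxonomy_tree` object: a node table (name, level code, parent,
#'   depth, leaf flag, db_size, accession, cultivated, habitat) in preorder,
#'   plus the stated root total if present.
#' @seealso [pmoa_taxonomy()] for the packaged pmoA/CuMMO instance.
#' @export
load_taxonomy_table <- function(x) {
  if (is.character(x)) {
    x <- read.delim(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", fill = TRUE,
                    quote = "", comment.char = "#")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("level_code", "name") %in% names(x)))
    stop("taxonomy table needs 'level_code' and 'name' columns")
  for (col in c("cultivated", "db_size", "accession", "habitat"))
    if (is.null(x[[col]])) x[[col]] <- ""
  code <- trimws(as.character(x$level_code))
  name <- trimws(as.character(x$name))
  keep <- nzchar(code) & nzchar(name)
  x <- x[keep, , drop = FALSE]
  code <- code[keep]; name <- name[keep]

  if (anyDuplicated(name)) {
    d <- name[duplicated(name)][1L]
    stop(sprintf("duplicate taxon name '%s' (level codes %s)", d,
                 paste(code[name == d], collapse = ", ")))
  }
  if (anyDuplicated(code)) {
    d <- code[duplicated(code)][1L]
    stop(sprintf("duplicate level code '%s' (names %s)", d,
                 paste(name[code == d], collapse = ", ")))
  }

  parts <- strsplit(code, ".", fixed = TRUE)
  depth <- lengths(parts)
  if (sum(depth == 1L) != 1L)
    stop("taxonomy must have exactly one root (single-component level code)")
  parent_code <- vapply(parts, function(p)
    paste(p[-length(p)], collapse = "."), character(1))
  parent <- rep(NA_character_, length(code))
  for (i in seq_along(code)) {
    if (depth[i] == 1L) next
    j <- match(parent_code[i], code)
    if (is.na(j))
      stop(sprintf("orphan level code '%s': parent code '%s' is missing",
                   code[i], parent_code[i]))
    parent[i] <- name[j]
  }

  db_size <- suppressWarnings(as.numeric(x$db_size))
  db_size[is.na(db_size) & !nzchar(trimws(x$db_size))] <- NA_real_
  if (any(!is.na(db_size) & db_size < 0))
    stop("negative db_size is not allowed")

  nodes <- data.frame(
    name = name, level_code = code, parent = parent, depth = depth,
    db_size = db_size,
    accession = trimws(as.character(x$accession)),
    cultivated = trimws(as.character(x$cultivated)),
    habitat = trimws(as.character(x$habitat)),
    stringsAsFactors = FALSE
  )
  nodes$is_leaf <- !(nodes$name %in% nodes$parent)

  stated_total <- NA_real_
  root <- which(nodes$depth == 1L)
  if (!is.na(nodes$db_size[root])) {
    stated_total <- nodes$db_size[root]
    nodes$db_size[root] <- NA_real_
  }
  bad <- !nodes$is_leaf & !is.na(nodes$db_size)
  if (any(bad))
    stop(sprintf("db_size on internal node(s): %s",
                 paste(nodes$name[bad], collapse = ", ")))
  new_taxonomy_tree(nodes, stated_total)
}

#' The packaged pmoA/CuMMO taxonomy
#'
#' Loads the curated 54-leaf hierarchy of pmoA and related CuMMO gene taxa
#' that ships with the package: 53 genus-level taxa under `MOB_like`
#' (Type Ia/Ib/Ic, Type IIa/IIb and the divergent pXMO_like clades) plus the
#' `AOB_like` out-group for co-amplified bacterial amoA.  Leaf rows carry the
#' curated reference-database sizes (summing to 6628 sequences) and one
#' representative accession each.
#'
#' @return A `taxonomy_tree`.
#' @export
pmoa_taxonomy <- function() {
  load_taxonomy_table(system.file("extdata", "pmoa_taxonomy.tsv",
                                  package = "pmoaclass", mustWork = TRUE))
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes (%d leaves), root '%s'\n",
              nrow(x$nodes), sum(x$nodes$is_leaf), taxon_root(x)))
  if (!is.na(x$stated_total))
    cat(sprintf("  stated reference total: %d\n", as.integer(x$stated_total)))
  invisible(x)
}

taxon_root <- function(tree) tree$nodes$name[tree$nodes$depth == 1L]

taxon_exists <- function(tree, name) name %in% tree$nodes$name

#' @rdname taxon_path
#' @export
taxon_is_leaf <- function(tree, name) {
  stopifnot(taxon_exists(tree, name))
  tree$nodes[name, "is_leaf"]
}

#' @rdname taxon_path
#' @export
taxon_children <- function(tree, name) {
  tree$nodes$name[!is.na(tree$nodes$parent) & tree$nodes$parent == name]
}

#' Tree navigation helpers
#'
#' `taxon_path()` returns the root-to-node name path, `taxon_leaves()` the
#' leaves of the subtree rooted at `name`, `taxon_lca()` the lowest common
#' ancestor of a set of node names, `taxon_children()` the ordered children
#' and `taxon_is_leaf()` the leaf flag.
#'
#' @param tree A `taxonomy_tree`.
#' @param name,names Node name(s) present in the tree.
#' @return Character vector of node names (`taxon_path`, `taxon_leaves`,
#'   `taxon_children`), a single name (`taxon_lca`) or a logical flag.
#' @export
taxon_path <- function(tree, name) {
  if (!taxon_exists(tree, name)) stop(sprintf("unknown taxon '%s'", name))
  path <- name
  p <- tree$nodes[name, "parent"]
  while (!is.na(p)) {
    path <- c(p, path)
    p <- tree$nodes[p, "parent"]
  }
  path
}

#' @rdname taxon_path
#' @export
taxon_leaves <- function(tree, name = taxon_root(tree)) {
  if (taxon_is_leaf(tree, name)) return(name)
  unlist(lapply(taxon_children(tree, name), taxon_leaves, tree = tree),
         use.names = FALSE)
}

#' @rdname taxon_path
#' @export
taxon_lca <- function(tree, names) {
  stopifnot(length(names) >= 1L)
  paths <- lapply(unique(names), taxon_path, tree = tree)
  k <- min(lengths(paths))
  common <- 0L
  for (i in seq_len(k)) {
    lev <- vapply(paths, `[`, character(1), i)
    if (all(lev == lev[1L])) common <- i else break
  }
  if (common == 0L) stop("nodes share no common ancestor")
  paths[[1L]][common]
}

is_ancestor_or_self <- function(tree, anc, node) {
  anc %in% taxon_path(tree, node)
}

#' Check leaf database sizes against the stated total
#'
#' Sums `db_size` over all leaves.  If the tree carries a stated root total
#' that differs from the recomputed sum, a warning of class
#' `pmoaclass_size_mismatch` is raised; when a `reference` tree is supplied,
#' the warning names the leaves whose sizes differ from it.
#'
#' @param tree A `taxonomy_tree` with populated leaf `db_size`.
#' @param reference Optional second `taxonomy_tree` to compare leaf-by-leaf.
#' @return The leaf `db_size` total (numeric).
#' @export
validate_db_sizes <- function(tree, reference = NULL) {
  leaves <- tree$nodes[tree$nodes$is_leaf, , drop = FALSE]
  if (anyNA(leaves$db_size))
    stop(sprintf("db_size missing for leaf(s): %s",
                 paste(leaves$name[is.na(leaves$db_size)], collapse = ", ")))
  if (any(leaves$db_size < 0)) stop("negative db_size is not allowed")
  total <- sum(leaves$db_size)
  if (!is.na(tree$stated_total) && total != tree$stated_total) {
    detail <- ""
    if (!is.null(reference)) {
      ref_leaves <- reference$nodes[reference$nodes$is_leaf, , drop = FALSE]
      shared <- intersect(leaves$name, ref_leaves$name)
      diff <- shared[leaves[shared, "db_size"] != ref_leaves[shared, "db_size"]]
      if (length(diff))
        detail <- sprintf("; leaves differing from reference: %s",
                          paste(diff, collapse = ", "))
    }
    warning(warningCondition(
      sprintf("leaf db_size total %d differs from stated total %d%s",
              as.integer(total), as.integer(tree$stated_total), detail),
      class = "pmoaclass_size_mismatch"))
  }
  total
}

# ---- Newick + map export/import -------------------------------------------

preorder_ids <- function(tree) {
  ids <- character(0)
  walk <- function(name) {
    ids <<- c(ids, name)
    for (ch in taxon_children(tree, name)) walk(ch)
  }
  walk(taxon_root(tree))
  setNames(seq_along(ids) - 1L, ids)
}

#' Write a taxonomy as a Newick tree plus identifier map
#'
#' Every node receives a numeric identifier assigned in depth-first preorder
#' starting at 0; the Newick string uses the identifiers as labels and the
#' map file translates identifier to name (`id<TAB>name`), the "alternative
#' taxonomy" dialect consumed by MEGAN.  [read_tree_and_map()] reconstructs
#' an isomorphic tree from the pair.
#'
#' @param tree A `taxonomy_tree`.
#' @param tre_path,map_path Output file paths.
#' @return Invisibly, a list with the Newick string and the map data frame.
#' @export
write_tree_and_map <- function(tree, tre_path, map_path) {
  ids <- preorder_ids(tree)
  nwk <- function(name) {
    ch <- taxon_children(tree, name)
    if (!length(ch)) return(as.character(ids[[name]]))
    paste0("(", paste(vapply(ch, nwk, character(1)), collapse = ","), ")",
           ids[[name]])
  }
  newick <- paste0(nwk(taxon_root(tree)), ";")
  writeLines(newick, tre_path)
  map <- data.frame(id = unname(ids), name = names(ids),
                    stringsAsFactors = FALSE)
  write.table(map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(list(newick = newick, map = map))
}

#' @rdname write_tree_and_map
#' @export
read_tree_and_map <- function(tre_path, map_path) {
  map <- read.delim(map_path, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "")
  id2name <- setNames(map[[2L]], map[[1L]])
  txt <- paste(readLines(tre_path), collapse = "")
  if (!grepl("(", txt, fixed = TRUE)) {
    # single-node tree: bare root label
    root_id <- sub(";.*$", "", trimws(txt))
    nodes <- data.frame(name = id2name[[root_id]], level_code = "0",
                        parent = NA_character_, depth = 1L,
                        db_size = NA_real_, accession = "", cultivated = "",
                        habitat = "", is_leaf = TRUE,
                        stringsAsFactors = FALSE)
    return(new_taxonomy_tree(nodes))
  }
  phy <- ape::read.tree(text = txt)
  ntip <- length(phy$tip.label)
  lab <- c(phy$tip.label, phy$node.label)
  edges <- phy$edge
  parent_of <- rep(NA_character_, length(lab))
  for (e in seq_len(nrow(edges)))
    parent_of[edges[e, 2L]] <- lab[edges[e, 1L]]
  name_of <- unname(id2name[lab])
  if (anyNA(name_of)) stop("map file does not cover all tree identifiers")
  parent_name <- ifelse(is.na(parent_of), NA, unname(id2name[parent_of]))
  # regenerate dotted level codes from the recovered topology
  children <- split(name_of, parent_name)
  root <- name_of[is.na(parent_name)]
  codes <- c(); depths <- c()
  walk <- function(name, code, depth) {
    codes[[name]] <<- code; depths[[name]] <<- depth
    ch <- children[[name]]
    for (i in seq_along(ch)) walk(ch[i], paste0(code, ".", i), depth + 1L)
  }
  walk(root, "0", 1L)
  ord <- names(codes)
  nodes <- data.frame(
    name = ord, level_code = unname(unlist(codes[ord])),
    parent = unname(setNames(parent_name, name_of)[ord]),
    depth = unname(unlist(depths[ord])), db_size = NA_real_,
    accession = "", cultivated = "", habitat = "",
    stringsAsFactors = FALSE)
  nodes$is_leaf <- !(nodes$name %in% nodes$parent)
  new_taxonomy_tree(nodes)
}

#' Are two taxonomies isomorphic on labels and topology?
#'
#' @param t1,t2 `taxonomy_tree` objects.
#' @return TRUE if both trees have the same node names and the same
#'   parent/child pairs (child order ignored).
#' @export
trees_isomorphic <- function(t1, t2) {
  setequal(t1$nodes$name, t2$nodes$name) &&
    identical(taxon_root(t1), taxon_root(t2)) &&
    setequal(paste(t1$nodes$parent, t1$nodes$name),
             paste(t2$nodes$parent, t2$nodes$name))
}
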