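# Reference database: taxon-labelled nucleotide sequences tied to a taxonomy.

fasta_lines <- function(headers, seqs) {
  if (!length(headers)) return(character(0))
  as.vector(rbind(paste0(">", headers), seqs))
}

#' Construct a reference database
#'
#' @param records data.frame with columns `accession`, `taxon`, `sequence`
#'   (nucleotide, A/C/G/T).
#' @param tree A `taxonomy_tree`; every record's taxon must resolve to one of
#'   its leaves.
#' @return A `reference_db` object.
#' @export
reference_db <- function(records, tree) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "taxon", "sequence") %in% names(records)))
  records$sequence <- toupper(records$sequence)
  if (any(nchar(records$sequence) == 0L)) stop("empty reference sequence")
  unknown <- setdiff(unique(records$taxon), tree$nodes$name)
  if (length(unknown))
    stop(sprintf("reference taxa not in tree: %s",
                 paste(unknown, collapse = ", ")))
  not_leaf <- unique(records$taxon[!vapply(records$taxon, taxon_is_leaf,
                                           logical(1), tree = tree)])
  if (length(not_leaf))
    stop(sprintf("reference taxa are not leaves: %s",
                 paste(not_leaf, collapse = ", ")))
  if (anyDuplicated(records$accession)) stop("duplicate accessions")
  rownames(records) <- NULL
  structure(list(records = records, tree = tree), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d sequences, %d taxa\n",
              nrow(x$records), length(unique(x$records$taxon))))
  invisible(x)
}

#' Read and write taxon-labelled reference FASTA
#'
#' The header dialect is BLAST-database style: the accession followed by the
#' leaf taxon in square brackets, e.g. `>AB222881 [JRC_3]`.
#'
#' @param db A `reference_db`.
#' @param path FASTA file path.
#' @param tree A `taxonomy_tree` used to validate taxa on read.
#' @return `read_reference_fasta` returns a `reference_db`;
#'   `write_reference_fasta` returns the path invisibly.
#' @export
write_reference_fasta <- function(db, path) {
  writeLines(fasta_lines(sprintf("%s [%s]", db$records$accession,
                                 db$records$taxon),
                         db$records$sequence), path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path, tree) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  m <- regmatches(nm, regexec("^(\\S+)\\s+\\[(.+)\\]", nm))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop(sprintf("FASTA header without 'accession [Taxon]' form: %s",
                 nm[bad][1L]))
  reference_db(data.frame(
    accession = vapply(m, `[`, character(1), 2L),
    taxon = vapply(m, `[`, character(1), 3L),
    sequence = as.character(seqs), stringsAsFactors = FALSE), tree)
}

#' Write mothur-style training files
#'
#' Emits the two files a mothur-compatible classifier trains from: a FASTA of
#' the reference sequences (ids only in the headers) and a taxonomy file with
#' one `id<TAB>Rank1;Rank2;...;Leaf;` line per sequence giving the
#' root-to-leaf path of its taxon.
#'
#' @param db A `reference_db`.
#' @param fasta_path,taxonomy_path Output paths.
#' @return Invisibly, the taxonomy data frame.
#' @export
write_mothur_style_files <- function(db, fasta_path, taxonomy_path) {
  paths <- vapply(db$records$taxon, function(tx)
    paste0(paste(taxon_path(db$tree, tx), collapse = ";"), ";"), character(1))
  writeLines(fasta_lines(db$records$accession, db$records$sequence),
             fasta_path)
  tax <- data.frame(id = db$records$accession, taxonomy = unname(paths),
                    stringsAsFactors = FALSE)
  write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(tax)
}

#' @rdname write_mothur_style_files
#' @export
read_mothur_taxonomy <- function(taxonomy_path) {
  if (length(readLines(taxonomy_path)) == 0L)
    return(data.frame(id = character(0), taxonomy = character(0),
                      leaf = character(0), stringsAsFactors = FALSE))
  tax <- read.delim(taxonomy_path, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "")
  names(tax) <- c("id", "taxonomy")
  ranks <- strsplit(sub(";$", "", tax$taxonomy), ";", fixed = TRUE)
  tax$leaf <- vapply(ranks, function(r) r[length(r)], character(1))
  tax
}

# ---- generic read FASTA ----------------------------------------------------

#' Read amplicon reads from FASTA into a data frame
#'
#' @param path FASTA file.
#' @param group_path Optional tab-delimited group file (`read_id<TAB>sample`);
#'   reads without an entry get sample `"sample1"`.
#' @return data.frame with columns `read_id`, `sample`, `sequence`.
#' @export
read_fasta_df <- function(path, group_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  sample <- rep("sample1", length(ids))
  if (!is.null(group_path)) {
    g <- read.delim(group_path, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "")
    sample <- ifelse(ids %in% g[[1L]], g[[2L]][match(ids, g[[1L]])], sample)
  }
  data.frame(read_id = ids, sample = sample,
             sequence = as.character(seqs), stringsAsFactors = FALSE)
}

#' Write reads to FASTA
#'
#' @param reads data.frame with `read_id` and `sequence` columns.
#' @param path Output path.
#' @export
write_reads_fasta <- function(reads, path) {
  writeLines(fasta_lines(reads$read_id, reads$sequence), path)
  invisible(path)
}

as_read_df <- function(reads) {
  if (is.character(reads) && !is.data.frame(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    reads <- data.frame(read_id = ids, sample = "sample1",
                        sequence = unname(reads), stringsAsFactors = FALSE)
  }
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  if (is.null(reads$sample)) reads$sample <- "sample1"
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  if (anyDuplicated(reads$read_id)) stop("duplicate read ids")
  reads
}
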