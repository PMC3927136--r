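# End-to-end workflow: filter -> (NBC and/or search+LCA) -> novelty ->
# per-sample summaries, with tabular artifacts and a machine-readable log.

#' Run the classification pipeline
#'
#' Executes quality filtering, optional name-list removal, classification by
#' the naive Bayesian classifier and/or nucleotide search plus LCA, novelty
#' tiering, and per-sample count tables, writing all artifacts into
#' `outdir`.  Identical inputs, configuration and seed produce byte-identical
#' artifacts.
#'
#' @param reads data.frame of reads, named character vector, or FASTA path.
#' @param db A `reference_db`.
#' @param outdir Output directory (created if missing).
#' @param method `"both"`, `"nbc"` or `"lca"`.
#' @param remove_names Optional read ids (or accnos file) to drop after
#'   filtering, e.g. an externally produced chimera list.
#' @param filter_args List of arguments for [quality_filter()].
#' @param nbc_cfg,search_cfg,lca_cfg,novelty_cfg Module configurations.
#' @param seed Integer seed (bootstrap resampling).
#' @return Invisibly, a list with the per-stage objects: `kept`, `rejected`,
#'   `nbc`, `hits`, `assignments`, `novelty`, `counts`, `agreement` (NBC vs
#'   LCA leaf-level agreement table when `method = "both"`), and `log`.
#' @export
run_pipeline <- function(reads, db, outdir, method = c("both", "nbc", "lca"),
                         remove_names = NULL, filter_args = list(),
                         nbc_cfg = nbc_config(), search_cfg = search_config(),
                         lca_cfg = lca_config(),
                         novelty_cfg = novelty_config(), seed = 1L) {
  method <- match.arg(method)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fasta_df(reads)
  reads <- as_read_df(reads)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  log <- c(sprintf("pmoaclass\t%s", as.character(utils::packageVersion("pmoaclass"))),
           sprintf("method\t%s", method), sprintf("seed\t%d", as.integer(seed)),
           sprintf("reads_in\t%d", nrow(reads)))

  flt <- do.call(quality_filter, c(list(reads), filter_args))
  kept <- flt$kept
  log <- c(log, sprintf("filter_kept\t%d", nrow(kept)),
           sprintf("filter_rejected\t%d", nrow(flt$rejected)))
  if (!is.null(remove_names)) {
    kept <- remove_by_name(kept, remove_names)
    log <- c(log, sprintf("removed_by_name\t%d", attr(kept, "n_removed")))
  }
  write_reads_fasta(kept, pth("filtered.fasta"))
  write.table(flt$rejected[c("read_id", "reason")], pth("rejected.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  out <- list(kept = kept, rejected = flt$rejected)
  if (!nrow(kept)) stop("pipeline: no reads survived filtering")

  if (method %in% c("both", "nbc")) {
    model <- nbc_train(db, nbc_cfg)
    nbc <- nbc_classify(model, kept, nbc_cfg, seed = seed)
    write.table(nbc[c("read_id", "path", "reported_taxon")], pth("nbc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$nbc <- nbc
    log <- c(log, sprintf("nbc_classified\t%d",
                          sum(nbc$reported_taxon != "unclassified")))
  }
  if (method %in% c("both", "lca")) {
    hits <- search_nucleotide(kept, db, search_cfg)
    write_hits_tsv(hits, pth("hits.tsv"))
    asg <- assign_lca_all(hits, db$tree, lca_cfg)
    write.table(asg, pth("assignments.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    nov <- tier_reads(kept, hits, db, db$tree, novelty_cfg, lca_cfg,
                      search_cfg)
    write.table(nov, pth("novelty.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$hits <- hits; out$assignments <- asg; out$novelty <- nov
    log <- c(log, sprintf("lca_assigned\t%d", sum(!is.na(asg$node))),
             sprintf("novelty_%s\t%d", names(table(nov$tier)),
                     as.integer(table(nov$tier))))
    by_sample <- split(asg, kept$sample[match(asg$read_id, kept$read_id)])
    counts <- build_count_table(by_sample, db$tree)
    write.table(cbind(sample = rownames(counts), as.data.frame(counts)),
                pth("counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$counts <- counts
  }
  if (method == "both") {
    agree <- data.frame(read_id = out$nbc$read_id,
                        nbc = out$nbc$reported_taxon,
                        lca = out$assignments$node[
                          match(out$nbc$read_id, out$assignments$read_id)],
                        stringsAsFactors = FALSE)
    agree$agree <- !is.na(agree$lca) & agree$nbc == agree$lca
    write.table(agree, pth("agreement.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$agreement <- agree
    log <- c(log, sprintf("nbc_lca_agree\t%d", sum(agree$agree)))
  }
  writeLines(log, pth("run_log.tsv"))
  out$log <- log
  invisible(out)
}
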