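# Versioned table output, run reports and SQLite export.

TSV_SCHEMA_VERSION <- 1L

#' Write / read a schema-versioned TSV
#'
#' Every table the pipeline writes carries a leading
#' `# platevdj_schema=<n>` line; the reader rejects unknown versions.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @export
write_tsv_versioned <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# platevdj_schema=%d", TSV_SCHEMA_VERSION), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv_versioned
#' @export
read_tsv_versioned <- function(path) {
  first <- readLines(path, n = 1L)
  v <- suppressWarnings(as.integer(sub("^# platevdj_schema=", "", first)))
  if (is.na(v) || !startsWith(first, "# platevdj_schema="))
    stop("not a versioned table: ", path)
  if (v != TSV_SCHEMA_VERSION)
    stop(sprintf("unsupported table schema version %d in %s", v, path))
  read.delim(path, skip = 1L, stringsAsFactors = FALSE)
}

#' Write run reports
#'
#' Emits the per-plate stage logs, ASV table, scored table, complexity
#' table, a FASTA of high-confidence pairs (headers
#' `sample_id|chain|score`) and a run-summary JSON with per-stage read
#' counts, bins per sample and the complexity distribution.
#'
#' @param results [process_run()] output.
#' @param outdir output directory (created if needed).
#' @return Invisible named vector of file paths.
#' @export
write_reports <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  f <- c(stage_logs = file.path(outdir, "stage_logs.tsv"),
         asv_table = file.path(outdir, "asv_table.tsv"),
         scored = file.path(outdir, "scored.tsv"),
         complexity = file.path(outdir, "complexity.tsv"),
         pairs_fasta = file.path(outdir, "high_confidence_pairs.fasta"),
         summary = file.path(outdir, "run_summary.json"))
  write_tsv_versioned(results$stage_logs, f[["stage_logs"]])
  write_tsv_versioned(results$asv_table, f[["asv_table"]])
  write_tsv_versioned(results$scored, f[["scored"]])
  write_tsv_versioned(results$complexity, f[["complexity"]])

  p <- results$pairs
  if (nrow(p)) {
    seqs <- c(rbind(p$light_nt, p$heavy_nt))
    hdrs <- c(rbind(sprintf("%s|light|%.3f", p$sample_id, p$light_score),
                    sprintf("%s|heavy|%.3f", p$sample_id, p$heavy_score)))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(seqs, hdrs)), f[["pairs_fasta"]])
  } else writeLines(character(0), f[["pairs_fasta"]])

  stage_totals <- stats::aggregate(
    cbind(reads_in, reads_out, reads_discarded) ~ stage,
    data = results$stage_logs, sum)
  stage_totals <- stage_totals[match(unique(results$stage_logs$stage),
                                     stage_totals$stage), ]
  bins_per_sample <- as.list(table(results$bins$sample_id))
  summary <- list(
    schema_version = TSV_SCHEMA_VERSION,
    n_plates = length(unique(results$stage_logs$plate)),
    stage_read_counts = stage_totals,
    bins_per_sample = bins_per_sample,
    complexity = as.list(setNames(results$complexity$complexity,
                                  results$complexity$sample_id)),
    n_high_confidence_pairs = nrow(results$pairs))
  jsonlite::write_json(summary, f[["summary"]], auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(f)
}

#' Export results to an SQLite database
#'
#' Tables: `samples` (IDs, replicate structure, complexity), `chains`
#' (reported nucleotide span, amino-acid sequence, the seven FR/CDR
#' segments), `scores` (ASV/match/total score, percentile, flags) and
#' `run_metadata`. Re-export to the same path is idempotent.
#'
#' @param results [process_run()] output.
#' @param path SQLite file path.
#' @param metadata optional named list written to `run_metadata`.
#' @return Invisible path.
#' @export
export_sqlite <- function(results, path, metadata = list()) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  s <- results$scored
  samples <- unique(data.frame(sample_id = s$sample_id, project = s$project,
                               parent = s$parent, subclone = s$subclone,
                               stringsAsFactors = FALSE))
  samples$complexity <- results$complexity$complexity[
    match(samples$sample_id, results$complexity$sample_id)]
  chains <- unique(s[, c("sample_id", "chain_class", "aa_vdomain",
                         "nt_reported", REGION_NAMES)])
  scores <- s[, c("sample_id", "plate", "well", "chain_class", "aa_vdomain",
                  "count", "asv_score", "br", "tr", "total_replicates",
                  "match_score", "total_score", "percentile",
                  "aberrant_flag", "verified", "high_confidence")]
  meta <- data.frame(
    key = c("schema_version", names(metadata)),
    value = c(as.character(TSV_SCHEMA_VERSION),
              vapply(metadata, as.character, character(1))),
    stringsAsFactors = FALSE)
  DBI::dbWriteTable(con, "samples", samples, overwrite = TRUE)
  DBI::dbWriteTable(con, "chains", chains, overwrite = TRUE)
  DBI::dbWriteTable(con, "scores", scores, overwrite = TRUE)
  DBI::dbWriteTable(con, "run_metadata", meta, overwrite = TRUE)
  invisible(path)
}

#' Read back an SQLite export
#'
#' @param path SQLite file written by [export_sqlite()].
#' @return Named list of the four tables.
#' @export
read_sqlite_export <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  meta <- DBI::dbReadTable(con, "run_metadata")
  v <- as.integer(meta$value[meta$key == "schema_version"])
  if (!identical(v, TSV_SCHEMA_VERSION))
    stop("unsupported database schema version: ", v)
  list(samples = DBI::dbReadTable(con, "samples"),
       chains = DBI::dbReadTable(con, "chains"),
       scores = DBI::dbReadTable(con, "scores"),
       run_metadata = meta)
}
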