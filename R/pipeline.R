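# End-to-end orchestration: cleaned reads -> ASVs -> annotated bins ->
# scores -> high-confidence pairs, either from an in-memory simulated run
# or from files via a run_config.

#' Process a run end to end
#'
#' Runs the full consolidation on a set of plates: the cleaning cascade,
#' per-well/chain ASV calling, annotation and amino-acid binning, the ASV
#' support filter, star-rating scoring with aberrant light-chain removal,
#' complexity, and high-confidence pair selection.
#'
#' @param plates list of plates; each needs `r1`, `r2` (read data.frames),
#'   `sample_sheet` (with `plate_id`, `well_id`, `sample_id`, `barcode`).
#'   A [generate_run()] output's `plates` component fits directly.
#' @param primer_table data.frame `chain`, `primer` or named vector.
#' @param tso TSO sequence.
#' @param ann an [annotator()].
#' @param thresholds threshold list (see [load_config()]); omitted entries
#'   take the documented defaults.
#' @param params a [scoring_params()].
#' @param verified optional verified-by-cloning keys (see [score_run()]).
#' @return List with `stage_logs`, `asv_table`, `chain_totals`,
#'   `annotated`, `bins` (support-filtered), `scored`, `pairs`,
#'   `complexity`, `params`.
#' @export
process_run <- function(plates, primer_table, tso, ann,
                        thresholds = list(), params = scoring_params(),
                        verified = NULL) {
  thr <- utils::modifyList(.default_thresholds(), thresholds)
  logs <- list()
  asvs <- list()
  for (p in plates) {
    if (is.null(p)) next
    barcodes <- p$sample_sheet[, c("well_id", "barcode")]
    st <- process_reads(p$r1, p$r2, barcodes, primer_table, tso,
                        min_overlap = thr$min_overlap,
                        max_mismatch_rate = thr$max_mismatch_rate,
                        barcode_mismatches = thr$barcode_mismatches,
                        primer_mismatches = thr$primer_mismatches,
                        tso_mismatches = thr$tso_mismatches,
                        q_min = thr$q_min, min_len = thr$min_len)
    pid <- p$sample_sheet$plate_id[1]
    logs[[pid]] <- cbind(plate = pid, st$log, stringsAsFactors = FALSE)
    asvs[[pid]] <- call_asvs(st$reads, p$sample_sheet,
                             max_hamming = thr$max_hamming,
                             abundance_ratio = thr$abundance_ratio)
  }
  asv_table <- do.call(rbind, unname(asvs))
  stage_logs <- do.call(rbind, unname(logs))
  rownames(asv_table) <- rownames(stage_logs) <- NULL

  totals <- chain_read_totals(asv_table)
  annotated <- annotate_asvs(asv_table, ann)
  if (is.null(annotated)) stop("no ASV could be annotated")
  bins <- asv_support_filter(bin_by_aa(annotated), totals,
                             min_support = thr$min_support)
  scored <- score_run(bins, params, verified = verified)
  pairs <- select_high_confidence_pairs(scored, params)
  scored$high_confidence <-
    paste(scored$sample_id, scored$aa_vdomain) %in%
    c(paste(pairs$sample_id, pairs$light_aa),
      paste(pairs$sample_id, pairs$heavy_aa))

  keep <- !scored$aberrant_flag
  cx <- do.call(rbind, lapply(split(scored[keep, , drop = FALSE],
                                    scored$sample_id[keep]), function(s)
    data.frame(sample_id = s$sample_id[1], complexity = complexity(s),
               stringsAsFactors = FALSE)))
  rownames(cx) <- NULL

  list(stage_logs = stage_logs, asv_table = asv_table, chain_totals = totals,
       annotated = annotated, bins = bins, scored = scored, pairs = pairs,
       complexity = cx, params = params)
}

#' Run the pipeline from a configuration file
#'
#' File-based front end over [process_run()]: loads FASTQ pairs, sample
#' sheets, barcode tables, the primer FASTA and (for the table backend)
#' the region table named in a [load_config()] configuration.
#'
#' @param config a `run_config` or a YAML path.
#' @param write when `TRUE`, [write_reports()] is called on `outdir`.
#' @return [process_run()] results.
#' @export
run_pipeline <- function(config, write = TRUE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  plates <- lapply(config$plates, function(pl) {
    ss <- utils::read.csv(pl$sample_sheet, stringsAsFactors = FALSE)
    if (is.null(ss$plate_id)) ss$plate_id <- pl$plate_id
    list(r1 = read_fastq(pl$r1), r2 = read_fastq(pl$r2), sample_sheet = ss)
  })
  primer_table <- read_primer_fasta(config$primers)
  ann <- if (config$annotator$backend == "table") {
    annotator("table", regions = read.delim(config$annotator$regions,
                                            stringsAsFactors = FALSE))
  } else annotator("motif")
  res <- process_run(plates, primer_table, config$tso, ann,
                     thresholds = config$thresholds, params = config$scoring)
  if (write) write_reports(res, config$outdir)
  res
}
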