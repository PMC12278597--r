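# The read-cleaning cascade: pair merging, well demultiplexing, chain
# assignment via constant-region primer excision, TSO removal, N exclusion,
# 3' quality trimming and minimum-length filtering, with per-stage read
# accounting. Stage order follows the amplicon architecture: barcode at the
# 5' end of the merged read, TSO after it, constant primer at the 3' end.

stage_log <- function(stage, reads_in, reads_out) {
  data.frame(stage = stage, reads_in = reads_in, reads_out = reads_out,
             reads_discarded = reads_in - reads_out, stringsAsFactors = FALSE)
}

.check_read_df <- function(reads) {
  bad <- nchar(reads$seq) != nchar(reads$qual)
  if (any(bad))
    stop("sequence/quality length mismatch for read ", reads$id[which(bad)[1]])
  invisible(reads)
}

#' Merge one read pair by overlap
#'
#' The mate is reverse-complemented, then every ungapped placement against
#' the forward read is scored; the best placement with overlap at least
#' `min_overlap` and mismatch rate at most `max_mismatch_rate` is merged.
#' Within the overlap the higher-quality base (and its quality) is kept.
#'
#' @param seq1,qual1 forward read and its Phred+33 quality string.
#' @param seq2,qual2 reverse read (as sequenced) and quality.
#' @param min_overlap minimum acceptable overlap length.
#' @param max_mismatch_rate maximum fraction of mismatching overlap bases.
#' @return List with `seq` and `qual` of the merged read, or `NULL` when no
#'   acceptable overlap exists.
#' @export
merge_read_pair <- function(seq1, qual1, seq2, qual2,
                            min_overlap = 20L, max_mismatch_rate = 0.1) {
  if (nchar(seq1) != nchar(qual1) || nchar(seq2) != nchar(qual2))
    stop("sequence/quality length mismatch")
  s2 <- revcomp(seq2)
  q2 <- paste(rev(strsplit(qual2, "")[[1]]), collapse = "")
  res <- cpp_merge_overlap(seq1, qual1, s2, q2, as.integer(min_overlap),
                           max_mismatch_rate)
  if (is.null(res)) NULL else res[c("seq", "qual")]
}

#' Merge all read pairs of a plate
#'
#' @param r1,r2 read data.frames (`id`, `seq`, `qual`) in matching order.
#' @inheritParams merge_read_pair
#' @return List with `reads` (merged read data.frame) and `log` (one
#'   stage-log row).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20L, max_mismatch_rate = 0.1) {
  stopifnot(nrow(r1) == nrow(r2))
  .check_read_df(r1); .check_read_df(r2)
  n <- nrow(r1)
  seqs <- quals <- character(n)
  keep <- logical(n)
  if (n) {
    s2 <- revcomp(r2$seq)
    q2 <- vapply(r2$qual, function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
    for (i in seq_len(n)) {
      res <- cpp_merge_overlap(r1$seq[i], r1$qual[i], s2[i], q2[i],
                               as.integer(min_overlap), max_mismatch_rate)
      if (!is.null(res)) {
        keep[i] <- TRUE
        seqs[i] <- res$seq
        quals[i] <- res$qual
      }
    }
  }
  reads <- data.frame(id = r1$id[keep], seq = seqs[keep], qual = quals[keep],
                      stringsAsFactors = FALSE)
  list(reads = reads, log = stage_log("merge_pairs", n, nrow(reads)))
}

#' Demultiplex merged reads by 5' well barcode
#'
#' The barcode is matched at the 5' end within `max_mismatches` and excised.
#' Reads matching no barcode, or tied between two barcodes at the best
#' distance, go to the unassigned pool.
#'
#' @param reads merged read data.frame.
#' @param barcode_table data.frame with columns `well_id`, `barcode`
#'   (equal-length, unique barcodes).
#' @param max_mismatches tolerated barcode mismatches (default 0: barcodes
#'   carry sample identity).
#' @return List with `reads` (assigned, with a `well` column and barcode
#'   removed), `unassigned`, and `log`.
#' @export
demultiplex <- function(reads, barcode_table, max_mismatches = 0L) {
  stopifnot(all(c("well_id", "barcode") %in% names(barcode_table)))
  if (anyDuplicated(barcode_table$barcode))
    stop("duplicate barcode in barcode table")
  bl <- unique(nchar(barcode_table$barcode))
  if (length(bl) != 1L) stop("barcodes must be equal-length within a plate")
  n <- nrow(reads)
  if (n == 0L) {
    return(list(reads = cbind(reads, well = character(0)),
                unassigned = reads, log = stage_log("demultiplex", 0L, 0L)))
  }
  prefix <- substr(reads$seq, 1L, bl)
  d <- vapply(barcode_table$barcode, function(b)
    cpp_count_mismatches(prefix, b), integer(n))
  d <- matrix(d, nrow = n)
  best <- apply(d, 1L, min)
  n_best <- rowSums(d == best)
  hit <- best <= max_mismatches & n_best == 1L
  well <- barcode_table$well_id[apply(d, 1L, which.min)]
  assigned <- reads[hit, , drop = FALSE]
  assigned$well <- well[hit]
  assigned$seq <- substring(assigned$seq, bl + 1L)
  assigned$qual <- substring(assigned$qual, bl + 1L)
  list(reads = assigned, unassigned = reads[!hit, , drop = FALSE],
       log = stage_log("demultiplex", n, nrow(assigned)))
}

#' Assign chain class by 3' constant-region primer and excise it
#'
#' Each primer in the table (cocktails allowed: several primers per chain)
#' is compared against the read's 3' end; the best match within
#' `max_mismatches` sets the chain label and is removed. Reads with no
#' acceptable primer, or tied between primers of different chain classes,
#' are discarded.
#'
#' @param reads read data.frame.
#' @param primer_table data.frame with columns `chain`, `primer`, or a named
#'   character vector chain -> primer.
#' @param max_mismatches tolerated primer mismatches (default 2).
#' @return List with `reads` (chain-labelled, primer excised), `discarded`,
#'   and `log`.
#' @export
assign_chain_and_excise <- function(reads, primer_table, max_mismatches = 2L) {
  if (!is.data.frame(primer_table))
    primer_table <- data.frame(chain = names(primer_table),
                               primer = unname(primer_table),
                               stringsAsFactors = FALSE)
  if (nrow(primer_table) == 0L) stop("empty primer table")
  n <- nrow(reads)
  if (n == 0L) {
    reads$chain <- character(0)
    return(list(reads = reads, discarded = reads,
                log = stage_log("assign_chain", 0L, 0L)))
  }
  d <- matrix(NA_integer_, n, nrow(primer_table))
  for (j in seq_len(nrow(primer_table))) {
    pl <- nchar(primer_table$primer[j])
    suffix <- substr(reads$seq, pmax(1L, nchar(reads$seq) - pl + 1L),
                     nchar(reads$seq))
    d[, j] <- cpp_count_mismatches(suffix, primer_table$primer[j])
  }
  best <- apply(d, 1L, min)
  hit <- best <= max_mismatches
  chain <- rep(NA_character_, n)
  plen <- rep(NA_integer_, n)
  for (i in which(hit)) {
    js <- which(d[i, ] == best[i])
    cls <- unique(primer_table$chain[js])
    if (length(cls) > 1L) { hit[i] <- FALSE; next }   # ambiguous chain: discard
    chain[i] <- cls
    plen[i] <- nchar(primer_table$primer[js[1L]])
  }
  assigned <- reads[hit, , drop = FALSE]
  assigned$chain <- chain[hit]
  cut <- nchar(assigned$seq) - plen[hit]
  assigned$seq <- substr(assigned$seq, 1L, cut)
  assigned$qual <- substr(assigned$qual, 1L, cut)
  list(reads = assigned, discarded = reads[!hit, , drop = FALSE],
       log = stage_log("assign_chain", n, nrow(assigned)))
}

#' Remove a 5' template-switch oligo
#'
#' A TSO occurrence at the read 5' end within `max_mismatches` is removed;
#' reads without one pass through unchanged (no read is discarded).
#'
#' @param reads read data.frame.
#' @param tso TSO sequence (non-empty).
#' @param max_mismatches tolerated mismatches (default 2).
#' @return List with `reads` and `log`.
#' @export
remove_tso <- function(reads, tso, max_mismatches = 2L) {
  stopifnot(is.character(tso), nchar(tso) > 0L)
  n <- nrow(reads)
  if (n) {
    tl <- nchar(tso)
    d <- cpp_count_mismatches(substr(reads$seq, 1L, tl), tso)
    hit <- d <= max_mismatches
    reads$seq[hit] <- substring(reads$seq[hit], tl + 1L)
    reads$qual[hit] <- substring(reads$qual[hit], tl + 1L)
  }
  list(reads = reads, log = stage_log("remove_tso", n, n))
}

#' Discard reads containing ambiguous bases
#'
#' Any `N` anywhere in the sequence discards the read.
#'
#' @param reads read data.frame.
#' @return List with `reads`, `discarded`, and `log`.
#' @export
filter_n <- function(reads) {
  keep <- !grepl("N", reads$seq, fixed = TRUE)
  list(reads = reads[keep, , drop = FALSE],
       discarded = reads[!keep, , drop = FALSE],
       log = stage_log("filter_n", nrow(reads), sum(keep)))
}

#' Trim low-quality 3' tails
#'
#' Trailing bases with quality below `q_min` are removed, stopping at the
#' first base from the 3' end with quality at least `q_min`. A fully
#' low-quality read becomes empty (and falls to the length filter).
#'
#' @param reads read data.frame.
#' @param q_min minimum retained Phred quality (default 10).
#' @return List with `reads` and `log`.
#' @export
quality_trim_3prime <- function(reads, q_min = 10L) {
  n <- nrow(reads)
  if (n) {
    cut <- vapply(reads$qual, function(q) {
      v <- utf8ToInt(q) - 33L
      keep <- which(v >= q_min)
      if (length(keep)) keep[length(keep)] else 0L
    }, integer(1), USE.NAMES = FALSE)
    reads$seq <- substr(reads$seq, 1L, cut)
    reads$qual <- substr(reads$qual, 1L, cut)
  }
  list(reads = reads, log = stage_log("quality_trim_3prime", n, n))
}

#' Minimum-length filter
#'
#' @param reads read data.frame.
#' @param min_len minimum retained length in bases (default 385).
#' @return List with `reads`, `discarded`, and `log`.
#' @export
length_filter <- function(reads, min_len = 385L) {
  keep <- nchar(reads$seq) >= min_len
  list(reads = reads[keep, , drop = FALSE],
       discarded = reads[!keep, , drop = FALSE],
       log = stage_log("length_filter", nrow(reads), sum(keep)))
}

#' Run the full cleaning cascade on one plate
#'
#' Applies, in order: pair merging, demultiplexing, chain assignment with
#' primer excision, TSO removal, N exclusion, 3' quality trimming and the
#' minimum-length filter, accumulating a stage log.
#'
#' @param r1,r2 read data.frames for the two mates.
#' @param barcode_table data.frame `well_id`, `barcode`.
#' @param primer_table data.frame `chain`, `primer` or named vector.
#' @param tso TSO sequence.
#' @param min_overlap,max_mismatch_rate pair-merging parameters.
#' @param barcode_mismatches,primer_mismatches,tso_mismatches match
#'   tolerances (defaults 0, 2, 2).
#' @param q_min,min_len trimming/length thresholds (defaults 10, 385).
#' @return List with `reads` (cleaned, with `well` and `chain` columns) and
#'   `log` (stage-log data.frame; every row satisfies
#'   `reads_in == reads_out + reads_discarded`).
#' @export
process_reads <- function(r1, r2, barcode_table, primer_table, tso,
                          min_overlap = 20L, max_mismatch_rate = 0.1,
                          barcode_mismatches = 0L, primer_mismatches = 2L,
                          tso_mismatches = 2L, q_min = 10L, min_len = 385L) {
  logs <- list()
  st <- merge_pairs(r1, r2, min_overlap, max_mismatch_rate)
  logs$merge <- st$log
  st <- demultiplex(st$reads, barcode_table, barcode_mismatches)
  logs$demux <- st$log
  st <- assign_chain_and_excise(st$reads, primer_table, primer_mismatches)
  logs$chain <- st$log
  st <- remove_tso(st$reads, tso, tso_mismatches)
  logs$tso <- st$log
  st <- filter_n(st$reads)
  logs$n <- st$log
  st <- quality_trim_3prime(st$reads, q_min)
  logs$qtrim <- st$log
  st <- length_filter(st$reads, min_len)
  logs$len <- st$log
  list(reads = st$reads, log = do.call(rbind, unname(logs)))
}
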