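# ASV calling: exact dereplication followed by a greedy Hamming/abundance
# collapse (UNOISE-style). The denoiser sits behind a pluggable interface so
# an external ASV caller can be substituted without touching downstream
# stages.

#' Dereplicate sequences
#'
#' @param seqs character vector of cleaned read sequences for one
#'   well+chain.
#' @return data.frame `seq`, `count`, sorted by count descending, ties by
#'   lexicographic sequence.
#' @export
derep <- function(seqs) {
  if (length(seqs) == 0L)
    return(data.frame(seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  tb <- table(seqs)
  out <- data.frame(seq = names(tb), count = as.integer(tb),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy Hamming/abundance denoising
#'
#' Walks the dereplicated list in decreasing abundance. A sequence within
#' `max_hamming` substitutions of an already-retained ASV, and whose count
#' is at most `abundance_ratio` times that ASV's dereplicated count, is
#' absorbed into it (counts summed; the most abundant qualifying parent
#' wins). Anything else founds a new ASV. Sequences of unequal length are
#' never compared (Hamming distance undefined) and so stay distinct.
#'
#' @param derep_df data.frame `seq`, `count` sorted by count descending
#'   (as returned by [derep()]).
#' @param max_hamming maximum substitution distance to a parent (default 2).
#' @param abundance_ratio maximum child/parent dereplicated-count ratio for
#'   absorption (default 0.1).
#' @return data.frame `seq`, `count`, `support_fraction`; counts sum to the
#'   input read total and support fractions to 1.
#' @export
denoise_asvs <- function(derep_df, max_hamming = 2L, abundance_ratio = 0.1) {
  n <- nrow(derep_df)
  if (n == 0L)
    return(data.frame(seq = character(0), count = integer(0),
                      support_fraction = numeric(0), stringsAsFactors = FALSE))
  if (is.unsorted(-derep_df$count))
    stop("derep_df must be sorted by count descending")
  parent_seq <- character(0)
  parent_count0 <- integer(0)   # dereplicated counts, for the ratio test
  parent_total <- integer(0)
  for (i in seq_len(n)) {
    s <- derep_df$seq[i]
    cnt <- derep_df$count[i]
    absorbed <- FALSE
    for (j in seq_along(parent_seq)) {   # parents in decreasing abundance
      if (cnt > abundance_ratio * parent_count0[j]) next
      h <- cpp_hamming(s, parent_seq[j])
      if (h >= 0L && h <= max_hamming) {
        parent_total[j] <- parent_total[j] + cnt
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) {
      parent_seq <- c(parent_seq, s)
      parent_count0 <- c(parent_count0, cnt)
      parent_total <- c(parent_total, cnt)
    }
  }
  out <- data.frame(seq = parent_seq, count = parent_total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  out$support_fraction <- out$count / sum(out$count)
  rownames(out) <- NULL
  out
}

#' Build the ASV table for a cleaned plate
#'
#' Dereplicates and denoises per well+chain.
#'
#' @param reads cleaned read data.frame with `well` and `chain` columns.
#' @param sample_sheet data.frame mapping `well_id` to `sample_id` (and
#'   `plate_id`).
#' @param max_hamming,abundance_ratio denoiser parameters.
#' @return data.frame with columns `plate`, `well`, `sample_id`, `chain`,
#'   `seq`, `count`, `support_fraction`.
#' @export
call_asvs <- function(reads, sample_sheet, max_hamming = 2L,
                      abundance_ratio = 0.1) {
  if (nrow(reads) == 0L)
    return(data.frame(plate = character(0), well = character(0),
                      sample_id = character(0), chain = character(0),
                      seq = character(0), count = integer(0),
                      support_fraction = numeric(0), stringsAsFactors = FALSE))
  key <- paste(reads$well, reads$chain, sep = "\r")
  out <- lapply(split(seq_len(nrow(reads)), key), function(idx) {
    asv <- denoise_asvs(derep(reads$seq[idx]), max_hamming, abundance_ratio)
    w <- reads$well[idx[1]]
    i <- match(w, sample_sheet$well_id)
    data.frame(plate = sample_sheet$plate_id[i] %||% NA_character_,
               well = w, sample_id = sample_sheet$sample_id[i],
               chain = reads$chain[idx[1]], asv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
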