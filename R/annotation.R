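# Translation, FR/CDR segmentation behind a pluggable annotator interface,
# region-based quality filtering, amino-acid binning, and extraction of the
# reported nucleotide span (IMGT 1-127 for light-type chains, 1-128 for
# heavy-type).

#' Translate in the best forward frame
#'
#' Translates all three forward frames and keeps the one with the longest
#' stop-free stretch, the candidate variable region. Returns `NULL` when no
#' frame offers a stop-free stretch of at least `min_aa` residues (i.e.
#' every frame has a stop inside any plausible variable domain).
#'
#' @param nt nucleotide sequence.
#' @param min_aa minimum stop-free stretch to accept a frame (default 90,
#'   shorter than any complete variable domain).
#' @return List with `aa` (full-frame translation), `frame` (0/1/2), or
#'   `NULL`.
#' @export
translate_best_frame <- function(nt, min_aa = 90L) {
  b <- .best_frames(nt, min_aa)
  if (is.na(b$frame[1])) return(NULL)
  list(aa = b$aa[1], frame = b$frame[1])
}

# Vectorised best-frame translation over many sequences (one S4 call per
# frame, not per sequence).
.best_frames <- function(seqs, min_aa = 90L) {
  n <- length(seqs)
  aa_mat <- matrix("", 3L, n)
  run_mat <- matrix(0L, 3L, n)
  for (f in 0:2) {
    sub <- substring(seqs, f + 1L)
    long_enough <- nchar(sub) >= 3L
    if (any(long_enough))
      aa_mat[f + 1L, long_enough] <- translate_nt(sub[long_enough])
    run_mat[f + 1L, ] <- vapply(strsplit(aa_mat[f + 1L, ], "*", fixed = TRUE),
                                function(r) if (length(r)) max(nchar(r)) else 0L,
                                integer(1))
  }
  best <- max.col(t(run_mat), ties.method = "first")
  ok <- run_mat[cbind(best, seq_len(n))] >= min_aa
  list(aa = ifelse(ok, aa_mat[cbind(best, seq_len(n))], NA_character_),
       frame = ifelse(ok, best - 1L, NA_integer_))
}

#' Construct an annotator backend
#'
#' Two backends are provided. `"table"` is driven by a region table (e.g.
#' [clone_region_table()] output or any data.frame with `chain` and
#' FR1..FR4/CDR1..CDR3 columns) and recognises a variable domain by exact
#' amino-acid match — the reference backend for synthetic data. `"motif"`
#' is a heuristic anchored on the conserved FR1/FR3 cysteines and the
#' [FW]G.G J-motif, for data without a region table; its internal
#' boundaries are approximate.
#'
#' @param backend `"table"` or `"motif"`.
#' @param regions region table (required for `"table"`).
#' @return An `annotator` object.
#' @export
annotator <- function(backend = c("table", "motif"), regions = NULL) {
  if (!is.character(backend) || !backend[1] %in% c("table", "motif"))
    stop("unknown annotator backend: ", backend[1])
  backend <- backend[1]
  if (backend == "table") {
    if (is.null(regions)) stop("the table backend requires a region table")
    stopifnot(all(c("chain", REGION_NAMES) %in% names(regions)))
    regions$v_aa <- do.call(paste0, regions[REGION_NAMES])
    regions <- regions[!duplicated(paste(regions$chain, regions$v_aa)), ,
                       drop = FALSE]
  }
  structure(list(backend = backend, regions = regions),
            class = c(paste0(backend, "_annotator"), "annotator"))
}

.annotated_chain <- function(aa_seq, chain_class, regions, v_start_aa,
                             nt = NULL, frame = NA_integer_) {
  region_lengths <- setNames(nchar(regions[REGION_NAMES]), REGION_NAMES)
  imgt_positions <- imgt_number_regions(region_lengths, chain_class)
  n <- sum(region_lengths)
  nt_vdomain <- NA_character_
  if (!is.null(nt) && !is.na(frame)) {
    start <- frame + 3L * (v_start_aa - 1L) + 1L
    nt_vdomain <- substr(nt, start, start + 3L * n - 1L)
  }
  chain <- structure(list(aa_seq = aa_seq, chain_class = chain_class,
                          regions = regions[REGION_NAMES],
                          imgt_positions = imgt_positions,
                          v_start_aa = v_start_aa, frame = frame,
                          nt_vdomain = nt_vdomain,
                          nt_reported = NA_character_),
                     class = "annotated_chain")
  if (!is.na(nt_vdomain)) chain$nt_reported <- extract_reported_nt(chain)
  chain
}

#' Annotate an amino-acid sequence
#'
#' Segments a translated sequence into FR1..FR4/CDR1..CDR3 with the given
#' backend and assigns IMGT-style numbering. When the source nucleotide
#' sequence and frame are supplied, the reported nucleotide span is also
#' extracted.
#'
#' @param aa amino-acid sequence (full translation; the variable domain may
#'   sit anywhere inside it).
#' @param ann an [annotator()].
#' @param nt optional source nucleotide sequence.
#' @param frame translation frame of `aa` within `nt`.
#' @return An `annotated_chain` (fields `aa_seq`, `chain_class`, `regions`,
#'   `imgt_positions`, `nt_reported`, `frame`) or `NULL` when the backend
#'   cannot place the sequence.
#' @export
annotate <- function(aa, ann, nt = NULL, frame = 0L) {
  stopifnot(inherits(ann, "annotator"))
  if (ann$backend == "table") .annotate_table(aa, ann, nt, frame)
  else .annotate_motif(aa, ann, nt, frame)
}

.annotate_table <- function(aa, ann, nt, frame) {
  for (i in seq_len(nrow(ann$regions))) {
    p <- regexpr(ann$regions$v_aa[i], aa, fixed = TRUE)
    if (p > 0L) {
      regs <- setNames(as.character(ann$regions[i, REGION_NAMES]), REGION_NAMES)
      return(.annotated_chain(aa, ann$regions$chain[i], regs,
                              v_start_aa = as.integer(p), nt = nt,
                              frame = frame))
    }
  }
  NULL
}

.annotate_motif <- function(aa, ann, nt, frame) {
  # J-motif ([FW]G.G) near the 3' end anchors FR4.
  m <- gregexpr("[FW]G.G", aa)[[1]]
  if (m[1] < 0L) return(NULL)
  for (fr4_start in rev(m)) {
    cys <- gregexpr("C", substr(aa, 1L, fr4_start - 1L), fixed = TRUE)[[1]]
    if (cys[1] < 0L || length(cys) < 2L) next
    # conserved Cys 104: last C giving a CDR3 of 5-13 residues
    c2 <- cys[fr4_start - cys - 1L >= 5L & fr4_start - cys - 1L <= 13L]
    if (!length(c2)) next
    c2 <- max(c2)
    # conserved Cys 23: earliest C at least 40 residues upstream of c2
    c1 <- cys[cys <= c2 - 40L & cys >= 20L]
    if (!length(c1)) next
    c1 <- min(c1)
    v_start <- c1 - 22L
    if (v_start < 1L) next
    fr1_end <- c1 + 3L
    fr4_len <- min(nchar(aa) - fr4_start + 1L,
                   if (substr(aa, fr4_start, fr4_start) == "W") 11L else 10L)
    chain_class <- if (substr(aa, fr4_start, fr4_start) == "W") "VH" else "VL"
    # canonical interior splits, adjusting CDR widths until the remainder
    # fits FR3's numbering window
    found <- FALSE
    for (cdr1_len in c(8L, 6:12)) {
      for (cdr2_len in c(7L, 4:10)) {
        fr3_len <- c2 - fr1_end - cdr1_len - 17L - cdr2_len
        if (fr3_len >= 1L && fr3_len <= 39L) {
          cdr1_end <- fr1_end + cdr1_len
          fr2_end <- cdr1_end + 17L
          cdr2_end <- fr2_end + cdr2_len
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) next
    cuts <- c(v_start, fr1_end, cdr1_end, fr2_end, cdr2_end, c2,
              fr4_start - 1L, fr4_start + fr4_len - 1L)
    regs <- setNames(substring(aa, c(cuts[1], cuts[2:7] + 1L),
                               cuts[2:8]), REGION_NAMES)
    if (any(nchar(regs) <= 0L)) next
    # window fit check; skip candidates the numbering cannot hold
    ok <- tryCatch({
      imgt_number_regions(setNames(nchar(regs), REGION_NAMES), chain_class)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
    return(.annotated_chain(aa, chain_class, regs, v_start_aa = v_start,
                            nt = nt, frame = frame))
  }
  NULL
}

#' Zero-length-region quality filter
#'
#' A chain with any framework or CDR region of zero length is discarded.
#'
#' @param chain an `annotated_chain`.
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
filter_zero_length_regions <- function(chain) {
  stopifnot(inherits(chain, "annotated_chain"))
  all(nchar(unlist(chain$regions[REGION_NAMES])) >= 1L)
}

#' Reported nucleotide span of an annotated chain
#'
#' The nucleotide bases corresponding to IMGT positions 1-127 (light-type
#' chains) or 1-128 (heavy-type). Missing leading or trailing positions
#' narrow the span; nothing is ever padded.
#'
#' @param chain an `annotated_chain` with `nt_vdomain` set.
#' @return Nucleotide string (possibly empty).
#' @export
extract_reported_nt <- function(chain) {
  stopifnot(inherits(chain, "annotated_chain"))
  if (is.na(chain$nt_vdomain)) stop("chain carries no nucleotide sequence")
  cap <- imgt_span_cap(chain$chain_class)
  sel <- which(chain$imgt_positions >= 1L & chain$imgt_positions <= cap)
  if (!length(sel)) return("")
  substr(chain$nt_vdomain, 3L * (min(sel) - 1L) + 1L, 3L * max(sel))
}

#' Annotate an ASV table
#'
#' Translates each ASV in its best frame, annotates it, and drops ASVs the
#' backend cannot place or that fail the zero-length-region filter.
#'
#' @param asv_table output of [call_asvs()].
#' @param ann an [annotator()].
#' @return data.frame: the annotatable ASV rows plus `chain_class`,
#'   `aa_vdomain`, one column per region, `nt_reported` and `imgt_start`/
#'   `imgt_end`.
#' @export
annotate_asvs <- function(asv_table, ann) {
  rows <- vector("list", nrow(asv_table))
  frames <- .best_frames(asv_table$seq)
  for (i in seq_len(nrow(asv_table))) {
    if (is.na(frames$frame[i])) next
    chain <- annotate(frames$aa[i], ann, nt = asv_table$seq[i],
                      frame = frames$frame[i])
    if (is.null(chain) || !filter_zero_length_regions(chain)) next
    rows[[i]] <- cbind(asv_table[i, , drop = FALSE],
                       data.frame(chain_class = chain$chain_class,
                                  aa_vdomain = paste(unlist(chain$regions),
                                                     collapse = ""),
                                  as.list(unlist(chain$regions)),
                                  nt_reported = chain$nt_reported,
                                  imgt_start = min(chain$imgt_positions),
                                  imgt_end = max(chain$imgt_positions),
                                  stringsAsFactors = FALSE))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bin annotated ASVs by identical amino-acid prediction
#'
#' ASVs of one well sharing chain class and region-concatenated amino-acid
#' sequence are collapsed into a bin: counts are summed and the most
#' abundant member (ties broken by lexicographic nucleotide sequence)
#' provides the representative nucleotide and reported span.
#'
#' @param annotated output of [annotate_asvs()].
#' @return data.frame with one row per (plate, well, chain_class,
#'   aa_vdomain) bin: region columns, `representative_nt`, `nt_reported`,
#'   `total_count`, `n_members`.
#' @export
bin_by_aa <- function(annotated) {
  key <- paste(annotated$plate, annotated$well, annotated$chain_class,
               annotated$aa_vdomain, sep = "\r")
  out <- lapply(split(seq_len(nrow(annotated)), key), function(idx) {
    sub <- annotated[idx, , drop = FALSE]
    rep_i <- idx[order(-sub$count, sub$seq)[1]]
    data.frame(plate = annotated$plate[rep_i], well = annotated$well[rep_i],
               sample_id = annotated$sample_id[rep_i],
               chain_class = annotated$chain_class[rep_i],
               aa_vdomain = annotated$aa_vdomain[rep_i],
               annotated[rep_i, REGION_NAMES, drop = FALSE],
               representative_nt = annotated$seq[rep_i],
               nt_reported = annotated$nt_reported[rep_i],
               total_count = sum(sub$count), n_members = nrow(sub),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$plate, out$well, out$chain_class, -out$total_count), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total cleaned reads per well and chain
#'
#' The denominator used both for the ASV support filter and for the ASV
#' score ("reads per primer well": all reads assigned to that chain's
#' primer class within the well).
#'
#' @param asv_table output of [call_asvs()] (counts over all ASVs equal the
#'   cleaned read counts).
#' @return data.frame `plate`, `well`, `chain`, `total_reads`.
#' @export
chain_read_totals <- function(asv_table) {
  agg <- stats::aggregate(count ~ plate + well + chain, data = asv_table, sum)
  names(agg)[names(agg) == "count"] <- "total_reads"
  agg
}

#' Minimum ASV-support filter
#'
#' Bins supported by fewer than `min_support` of the well+chain reads are
#' eliminated before scoring. The threshold is inclusive: support exactly
#' at the minimum is retained.
#'
#' @param bins output of [bin_by_aa()].
#' @param totals output of [chain_read_totals()].
#' @param min_support minimum support fraction (default 0.10).
#' @return The retained bins with a `support` column added.
#' @export
asv_support_filter <- function(bins, totals, min_support = 0.10) {
  i <- match(paste(bins$plate, bins$well, bins$chain_class),
             paste(totals$plate, totals$well, totals$chain))
  bins$support <- bins$total_count / totals$total_reads[i]
  bins[!is.na(bins$support) & bins$support >= min_support, , drop = FALSE]
}
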