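# The star-rating confidence system: sample-ID parsing, biological/
# technical replicate counting, ASV / match / total scores, run-wide
# aberrant light-chain removal, complexity, percentiles and high-confidence
# pair selection.

#' Scoring parameters
#'
#' @param mu ceiling of the ASV-derived score component (default 2).
#' @param lam ceiling of the match-derived component (default 3);
#'   `mu + lam` must equal 5, the star-rating maximum.
#' @param nu technical-replicate weight in `[0, 1]`: 1 makes a TR count
#'   like a BR in the match numerator, 0 gives TRs no direct reward (they
#'   still reduce the coverage penalty).
#' @param high_conf_threshold strict lower bound for high confidence
#'   (default 4).
#' @param aberrant_prevalence sample-prevalence threshold above which a
#'   light chain is treated as aberrant (default 0.5).
#' @param literal_max when `TRUE`, [total_score()] evaluates the published
#'   closed form `max(lam, ln(match)) + mu * asv` verbatim instead of the
#'   clamped default; kept for auditability (the literal form cannot score
#'   below `lam`).
#' @return A validated `scoring_params` list.
#' @export
scoring_params <- function(mu = 2, lam = 3, nu = 1, high_conf_threshold = 4,
                           aberrant_prevalence = 0.5, literal_max = FALSE) {
  if (abs(mu + lam - 5) > 1e-12) stop("mu + lam must equal 5")
  if (nu < 0 || nu > 1) stop("nu must be in [0, 1]")
  structure(list(mu = mu, lam = lam, nu = nu,
                 high_conf_threshold = high_conf_threshold,
                 aberrant_prevalence = aberrant_prevalence,
                 literal_max = isTRUE(literal_max)),
            class = "scoring_params")
}

#' Parse a sample identifier
#'
#' Identifiers follow `Project/Parent.subclone` (e.g. a hybridoma mAb ID);
#' the split is on the first `/` and the last `.`, and the subclone part is
#' optional.
#'
#' @param raw sample ID string(s).
#' @return For a single input, a list with `project`, `parent`, `subclone`
#'   (`NA` when absent) and `raw`; for a vector, a data.frame of the same
#'   fields.
#' @export
parse_sample_id <- function(raw) {
  slash <- regexpr("/", raw, fixed = TRUE)
  if (any(slash < 0L))
    stop("cannot parse sample ID (missing '/'): ",
         raw[which(slash < 0L)[1]])
  project <- substr(raw, 1L, slash - 1L)
  rest <- substring(raw, slash + 1L)
  dot <- vapply(gregexpr(".", rest, fixed = TRUE), function(p)
    if (p[1] < 0L) -1L else p[length(p)], integer(1))
  parent <- ifelse(dot > 0L, substr(rest, 1L, dot - 1L), rest)
  subclone <- ifelse(dot > 0L, substring(rest, dot + 1L), NA_character_)
  out <- data.frame(project = project, parent = parent, subclone = subclone,
                    raw = raw, stringsAsFactors = FALSE)
  if (length(raw) == 1L) as.list(out) else out
}

#' Count biological and technical replicates supporting a sequence
#'
#' Within a replicate group (all samples sharing project and parent), the
#' samples containing a sequence are split into biological replicates
#' (distinct subclones) and technical replicates (further samples of an
#' already-counted subclone). Samples without a subclone part are treated
#' as one shared empty subclone, so two of them are TRs of each other.
#'
#' @param supporting_subclones character vector: the subclone ID of every
#'   supporting sample (one entry per supporting sample; `NA` allowed).
#' @param group_size total number of samples in the replicate group.
#' @return List with `br`, `tr`, `total_replicates`.
#' @export
count_replicates <- function(supporting_subclones, group_size) {
  n <- length(supporting_subclones)
  if (n > group_size) stop("more supporting samples than the group holds")
  sub <- ifelse(is.na(supporting_subclones), "", supporting_subclones)
  br <- length(unique(sub))
  if (n == 0L) br <- 0L
  list(br = br, tr = n - br, total_replicates = as.integer(group_size))
}

#' ASV score
#'
#' Read support of a sequence within its well: reads per sequence divided
#' by the total reads assigned to that chain's primer class in the well.
#'
#' @param reads_per_sequence reads attributed to the sequence.
#' @param reads_per_primer_well total well reads for the chain's primer.
#' @return Fraction in `[0, 1]`.
#' @export
asv_score <- function(reads_per_sequence, reads_per_primer_well) {
  stopifnot(reads_per_primer_well > 0,
            reads_per_sequence >= 0,
            reads_per_sequence <= reads_per_primer_well)
  reads_per_sequence / reads_per_primer_well
}

#' Match score
#'
#' Cross-replicate support: `(BR + nu * TR) - (1 - (BR + TR) / Total)`.
#' The first term rewards matching replicates (technical ones weighted by
#' `nu`); the second penalises incomplete coverage of the replicate group
#' and is always computed on unweighted counts.
#'
#' @param br,tr biological / technical replicate counts.
#' @param total_replicates size of the replicate group (`>= br + tr`).
#' @param nu technical-replicate weight in `[0, 1]`.
#' @return Numeric score (can be non-positive for weak support).
#' @export
match_score <- function(br, tr, total_replicates, nu = 1) {
  stopifnot(total_replicates >= 1, br + tr <= total_replicates,
            nu >= 0, nu <= 1)
  (br + nu * tr) - (1 - (br + tr) / total_replicates)
}

#' Total (star) score
#'
#' Combines the match and ASV components. In the default mode the match
#' component is `ln(match)` clamped into `[0, lam]` (non-positive match
#' scores contribute 0), so the total lives in `[0, 5]` with the component
#' ceilings `lam` and `mu`. With `literal_max = TRUE` in the parameters,
#' the closed form `max(lam, ln(match)) + mu * asv` is evaluated verbatim
#' instead.
#'
#' @param match match score.
#' @param asv ASV score in `[0, 1]`.
#' @param params a [scoring_params()].
#' @return Numeric total score.
#' @export
total_score <- function(match, asv, params = scoring_params()) {
  stopifnot(inherits(params, "scoring_params"), asv >= 0, asv <= 1)
  if (params$literal_max) {
    lnm <- suppressWarnings(log(match))
    lnm[!is.finite(lnm)] <- -Inf
    return(pmax(params$lam, lnm) + params$mu * asv)
  }
  lnm <- suppressWarnings(log(pmax(match, 0)))
  comp <- pmin(pmax(lnm, 0), params$lam)
  comp[!is.finite(comp)] <- 0
  comp + params$mu * asv
}

#' Flag run-wide aberrant light chains
#'
#' A light-type amino-acid sequence present in strictly more than
#' `prevalence_threshold` of the run's samples is flagged as the aberrant
#' light chain (e.g. the non-functional Sp2/0 myeloma light chain that
#' contaminates hybridoma wells) and excluded from reporting and pairing.
#' Heavy-type chains are never flagged.
#'
#' @param entries scored/binned table with columns `chain_class`,
#'   `aa_vdomain` and a per-sample well identifier (`plate` + `well`).
#' @param prevalence_threshold flagging threshold (default 0.5).
#' @return `entries` with a logical `aberrant_flag` column.
#' @export
remove_aberrant_light_chains <- function(entries, prevalence_threshold = 0.5) {
  wells <- unique(paste(entries$plate, entries$well))
  n_samples <- length(wells)
  entries$aberrant_flag <- FALSE
  if (n_samples == 0L) return(entries)
  light <- chain_type(entries$chain_class) == "light"
  if (any(light)) {
    prev <- tapply(paste(entries$plate, entries$well)[light],
                   entries$aa_vdomain[light],
                   function(w) length(unique(w)) / n_samples)
    bad <- names(prev)[prev > prevalence_threshold]
    entries$aberrant_flag <- light & entries$aa_vdomain %in% bad
  }
  entries
}

#' Sample complexity
#'
#' The number of possible chain pairings for a sample: count of distinct
#' light-type sequences times count of distinct heavy-type sequences.
#'
#' @param entries entries of one sample (rows with `chain_class`,
#'   `aa_vdomain`; flagged aberrant rows should be excluded beforehand).
#' @return Integer count.
#' @export
complexity <- function(entries) {
  ct <- chain_type(entries$chain_class)
  n_l <- length(unique(entries$aa_vdomain[ct == "light"]))
  n_h <- length(unique(entries$aa_vdomain[ct == "heavy"]))
  as.integer(n_l * n_h)
}

#' Empirical percentile of a score
#'
#' Fraction of the population strictly below the score (the population
#' includes the entry itself; a singleton therefore sits at percentile 0).
#'
#' @param score score value(s).
#' @param population scores of the same chain type across the run.
#' @return Fraction(s) in `[0, 1)`.
#' @export
score_percentile <- function(score, population) {
  vapply(score, function(s) mean(population < s), numeric(1))
}

#' Score a run of filtered chain bins
#'
#' Computes, for every retained bin: BR/TR counts within its
#' project+parent replicate group, the ASV, match and total scores,
#' run-wide aberrant light-chain flags, and within-chain-class percentiles
#' (flagged entries are excluded from the percentile population).
#'
#' @param bins support-filtered bins ([asv_support_filter()] output; the
#'   `support` column is the ASV score).
#' @param params a [scoring_params()].
#' @param verified optional character vector of `sample_id|chain_class|aa`
#'   keys verified by cloning; matching entries are marked `verified`.
#' @return Scored data.frame with columns `sample_id`, `chain_class`,
#'   `aa_vdomain`, `nt_reported`, `count`, `asv_score`, `br`, `tr`,
#'   `total_replicates`, `match_score`, `total_score`, `percentile`,
#'   `aberrant_flag`, `verified` (plus provenance columns).
#' @export
score_run <- function(bins, params = scoring_params(), verified = NULL) {
  ids <- parse_sample_id(bins$sample_id)
  bins$project <- ids$project
  bins$parent <- ids$parent
  bins$subclone <- ids$subclone
  bins$well_uid <- paste(bins$plate, bins$well)

  group_key <- paste(bins$project, bins$parent)
  group_wells <- tapply(bins$well_uid, group_key,
                        function(w) length(unique(w)))

  # replicate counts per (group, chain_class, aa) sequence
  seq_key <- paste(group_key, bins$chain_class, bins$aa_vdomain, sep = "\r")
  first <- !duplicated(seq_key)
  rep_tab <- do.call(rbind, lapply(which(first), function(i) {
    k <- seq_key[i]
    rows <- bins[seq_key == k, , drop = FALSE]
    rows <- rows[!duplicated(rows$well_uid), , drop = FALSE]
    rc <- count_replicates(rows$subclone, group_wells[[group_key[i]]])
    data.frame(key = k, br = rc$br, tr = rc$tr,
               total_replicates = rc$total_replicates,
               stringsAsFactors = FALSE)
  }))
  m <- match(seq_key, rep_tab$key)
  bins$br <- rep_tab$br[m]
  bins$tr <- rep_tab$tr[m]
  bins$total_replicates <- rep_tab$total_replicates[m]

  bins$asv_score <- bins$support
  bins$match_score <- mapply(match_score, bins$br, bins$tr,
                             bins$total_replicates, MoreArgs = list(nu = params$nu))
  bins$total_score <- total_score(bins$match_score, bins$asv_score, params)

  bins <- remove_aberrant_light_chains(bins, params$aberrant_prevalence)

  bins$verified <- if (is.null(verified)) FALSE else
    paste(bins$sample_id, bins$chain_class, bins$aa_vdomain, sep = "|") %in% verified

  bins$percentile <- NA_real_
  for (ct in c("light", "heavy")) {
    sel <- chain_type(bins$chain_class) == ct & !bins$aberrant_flag
    if (any(sel))
      bins$percentile[sel] <- score_percentile(bins$total_score[sel],
                                               bins$total_score[sel])
  }
  names(bins)[names(bins) == "total_count"] <- "count"
  bins
}

#' Select high-confidence heavy/light pairs
#'
#' Per sample, the light and heavy chains with total score strictly above
#' the threshold qualify (entries verified by cloning qualify regardless of
#' score); when several qualify for a chain the maximum-scoring one is kept
#' (ties: higher ASV score, then lexicographic nucleotide sequence).
#' Flagged aberrant chains never qualify. Pairs whose light or heavy
#' amino-acid sequence recurs in another selected pair are then dropped, so
#' reported pairings are unique.
#'
#' @param scored output of [score_run()].
#' @param params a [scoring_params()].
#' @return data.frame with one row per retained pair: `sample_id`,
#'   `light_aa`, `heavy_aa`, `light_nt`, `heavy_nt`, `light_score`,
#'   `heavy_score`.
#' @export
select_high_confidence_pairs <- function(scored, params = scoring_params()) {
  thr <- params$high_conf_threshold
  ok <- !scored$aberrant_flag & (scored$total_score > thr | scored$verified)
  cand <- scored[ok, , drop = FALSE]
  empty <- data.frame(sample_id = character(0), light_aa = character(0),
                      heavy_aa = character(0), light_nt = character(0),
                      heavy_nt = character(0), light_score = numeric(0),
                      heavy_score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(empty)
  # dedupe TR wells of a sample: keep the best-scoring entry per sequence
  o <- order(cand$sample_id, cand$chain_class, cand$aa_vdomain,
             -cand$total_score, -cand$asv_score, cand$nt_reported)
  cand <- cand[o, , drop = FALSE]
  cand <- cand[!duplicated(paste(cand$sample_id, cand$chain_class,
                                 cand$aa_vdomain)), , drop = FALSE]
  pairs <- lapply(split(cand, cand$sample_id), function(s) {
    best <- function(ct) {
      sub <- s[chain_type(s$chain_class) == ct, , drop = FALSE]
      if (nrow(sub) == 0L) return(NULL)
      sub[order(-sub$total_score, -sub$asv_score, sub$nt_reported)[1], ,
          drop = FALSE]
    }
    l <- best("light"); h <- best("heavy")
    if (is.null(l) || is.null(h)) return(NULL)
    data.frame(sample_id = l$sample_id, light_aa = l$aa_vdomain,
               heavy_aa = h$aa_vdomain, light_nt = l$nt_reported,
               heavy_nt = h$nt_reported, light_score = l$total_score,
               heavy_score = h$total_score, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs)) return(empty)
  # uniqueness across pairs: a shared light or heavy sequence drops both.
  # Samples of the same parent line legitimately share chains, so
  # uniqueness is enforced across distinct parent groups.
  grp <- with(parse_sample_id(pairs$sample_id), paste(project, parent))
  dup_l <- ave(grp, pairs$light_aa, FUN = function(g) length(unique(g))) > 1
  dup_h <- ave(grp, pairs$heavy_aa, FUN = function(g) length(unique(g))) > 1
  pairs <- pairs[!(dup_l | dup_h), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}
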