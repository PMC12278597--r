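# IMGT-style integer numbering used throughout the package.
#
# Variable domains are segmented into FR1..FR4 / CDR1..CDR3 and numbered by
# fixed per-region windows emulating the IMGT unique numbering: FR1 starts at
# position 1, the FR3 conserved cysteine is anchored at 104, FR4 is anchored
# at its 3' end so a fully covered light-type chain ends at 127 and a
# heavy-type chain at 128. Insertion codes are not used, so region lengths
# must fit their windows (CDR3 at most 13 residues under this convention).

imgt_windows <- function(chain_class) {
  fr4_end <- imgt_span_cap(chain_class)
  list(FR1  = c(1L, 26L),  CDR1 = c(27L, 38L), FR2 = c(39L, 55L),
       CDR2 = c(56L, 65L), FR3  = c(66L, 104L), CDR3 = c(105L, 117L),
       FR4  = c(118L, fr4_end))
}

# Regions anchored at the window start, except FR3 and FR4 which are anchored
# at the window end (conserved Cys 104 and the J-region terminus).
END_ANCHORED_REGIONS <- c("FR3", "FR4")

#' IMGT positions for a segmented variable domain
#'
#' Assigns an integer IMGT-style position to every residue of a variable
#' domain given its seven region lengths, using the package's fixed-window
#' numbering convention.
#'
#' @param region_lengths named integer vector with entries FR1, CDR1, FR2,
#'   CDR2, FR3, CDR3, FR4 (residue counts).
#' @param chain_class one of `"VL"`, `"VH"`, `"alpha"`, `"beta"`, `"gamma"`,
#'   `"delta"`.
#' @return Integer vector, one position per residue of the concatenated
#'   regions, strictly increasing.
#' @export
imgt_number_regions <- function(region_lengths, chain_class) {
  stopifnot(all(REGION_NAMES %in% names(region_lengths)))
  win <- imgt_windows(chain_class)
  pos <- integer(0)
  for (r in REGION_NAMES) {
    n <- as.integer(region_lengths[[r]])
    w <- win[[r]]
    if (n > w[2] - w[1] + 1L)
      stop(sprintf("region %s length %d exceeds its numbering window (%d-%d)",
                   r, n, w[1], w[2]))
    if (n > 0L) {
      p <- if (r %in% END_ANCHORED_REGIONS) seq.int(w[2] - n + 1L, w[2])
           else seq.int(w[1], w[1] + n - 1L)
      pos <- c(pos, p)
    }
  }
  pos
}
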