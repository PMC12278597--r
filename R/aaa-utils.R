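# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Chain classes grouped by the span convention used for reported nucleotide
# sequences: light-type chains cover IMGT 1-127, heavy-type 1-128.
LIGHT_TYPE_CHAINS <- c("VL", "alpha", "gamma")
HEAVY_TYPE_CHAINS <- c("VH", "beta", "delta")
CHAIN_CLASSES <- c(LIGHT_TYPE_CHAINS, HEAVY_TYPE_CHAINS)
REGION_NAMES <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

chain_type <- function(chain_class) {
  ifelse(chain_class %in% LIGHT_TYPE_CHAINS, "light",
         ifelse(chain_class %in% HEAVY_TYPE_CHAINS, "heavy", NA_character_))
}

imgt_span_cap <- function(chain_class) {
  ifelse(chain_type(chain_class) == "light", 127L, 128L)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# n random codons, none of them stops.
random_codons <- function(n) {
  if (n == 0L) return("")
  cod <- character(n)
  for (i in seq_len(n)) {
    repeat {
      c3 <- random_dna(3L)
      if (!c3 %in% STOP_CODONS) break
    }
    cod[i] <- c3
  }
  paste(cod, collapse = "")
}

# One fixed codon per amino acid, for planting specific residues.
AA_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

aa_to_nt <- function(aa) {
  if (nchar(aa) == 0L) return("")
  paste(AA_CODON[strsplit(aa, "")[[1]]], collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

translate_nt <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (any(n < 3L)) stop("sequence too short to translate")
  as.character(Biostrings::translate(Biostrings::DNAStringSet(substr(x, 1L, n)),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

qual_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_qual <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
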