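# FASTQ / FASTA I/O. Reads are carried through the cascade as plain
# data.frames (id, seq, qual) with Phred+33 quality strings.

#' Read a FASTQ file into a read data.frame
#'
#' @param path FASTQ path, optionally gzipped.
#' @return data.frame with columns `id`, `seq`, `qual` (Phred+33).
#' @export
read_fastq <- function(path) {
  # the reader warns about dropping (empty) mcols on construction
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read data.frame to FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  # the constructor warns about dropping (empty) mcols; nothing is lost
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual)))
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a chain-class primer set to FASTA
#'
#' Headers follow the `>CHAINCLASS|name` convention.
#'
#' @param primer_set named character vector (chain class -> primer) or a
#'   data.frame with columns `chain`, `primer` and optionally `name`.
#' @param path output FASTA path.
#' @export
write_primer_fasta <- function(primer_set, path) {
  if (is.data.frame(primer_set)) {
    nm <- primer_set$name %||% primer_set$chain
    headers <- paste0(primer_set$chain, "|", nm)
    seqs <- primer_set$primer
  } else {
    headers <- paste0(names(primer_set), "|", names(primer_set))
    seqs <- unname(primer_set)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(seqs, headers)),
                              path)
  invisible(path)
}

#' Read a primer FASTA into a primer table
#'
#' @param path FASTA path with `>CHAINCLASS|name` headers.
#' @return data.frame with columns `chain`, `name`, `primer`.
#' @export
read_primer_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  data.frame(chain = vapply(parts, `[`, "", 1L),
             name = vapply(parts, function(p) p[min(2L, length(p))], ""),
             primer = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}
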