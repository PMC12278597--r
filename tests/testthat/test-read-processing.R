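test_that("overlap merging reconstructs a hand-built amplicon", {
  # r1 suffix GTACGTAA overlaps r2rc prefix: merged = ACGTACGTAACC
  r2rc <- "GTACGTAACC"
  m <- merge_read_pair("ACGTACGTAA", qstr(rep(30, 10)),
                       platevdj:::revcomp(r2rc), qstr(rep(30, 10)),
                       min_overlap = 6)
  expect_equal(m$seq, "ACGTACGTAACC")

  # no acceptable overlap
  expect_null(merge_read_pair("AAAAAAAAAA", qstr(rep(30, 10)),
                              platevdj:::revcomp("CCCCCCCCCC"),
                              qstr(rep(30, 10)), min_overlap = 6))

  # identical reads, full overlap: merged length equals read length
  m2 <- merge_read_pair("ACGTACGTAC", qstr(rep(30, 10)),
                        platevdj:::revcomp("ACGTACGTAC"), qstr(rep(30, 10)),
                        min_overlap = 6)
  expect_equal(nchar(m2$seq), 10L)

  expect_error(merge_read_pair("ACGT", qstr(rep(30, 3)), "ACGT",
                               qstr(rep(30, 4))), "length mismatch")
})

test_that("the higher-quality base wins inside the overlap", {
  # single mismatch in an 8-base full overlap; r2 has the better quality
  r1 <- "ACGTACGT"
  r2rc <- "ACGTACCT"  # differs at position 7
  m <- merge_read_pair(r1, qstr(rep(20, 8)), platevdj:::revcomp(r2rc),
                       qstr(rep(35, 8)), min_overlap = 6,
                       max_mismatch_rate = 0.2)
  expect_equal(substr(m$seq, 7, 7), "C")
  expect_equal(utf8ToInt(substr(m$qual, 7, 7)) - 33L, 35L)
})

test_that("demultiplexing assigns, excises, and refuses ambiguity", {
  bc <- data.frame(well_id = c("A1", "A2"),
                   barcode = c("ACGTACGT", "TGCATGCA"),
                   stringsAsFactors = FALSE)
  reads <- read_df(c(paste0("ACGTACGT", "GGGGCCCC"),
                     paste0("NNNNNNNN", "GGGGCCCC")))
  d <- demultiplex(reads, bc, max_mismatches = 0)
  expect_equal(d$reads$well, "A1")
  expect_equal(d$reads$seq, "GGGGCCCC")        # barcode removed
  expect_equal(nrow(d$unassigned), 1L)          # all-N barcode region

  # equidistant between two barcodes at 1 mismatch -> unassigned
  bc2 <- data.frame(well_id = c("A1", "A2"),
                    barcode = c("AAAAAAAA", "AAAAAACC"),
                    stringsAsFactors = FALSE)
  tie <- read_df(paste0("AAAAAAAC", "GGGG"))
  d2 <- demultiplex(tie, bc2, max_mismatches = 1)
  expect_equal(nrow(d2$reads), 0L)
  expect_equal(nrow(d2$unassigned), 1L)

  expect_error(demultiplex(reads, rbind(bc, bc[1, ])), "duplicate barcode")
})

test_that("chain assignment uses the best 3' primer and drops cross-chain ties", {
  primers <- data.frame(chain = c("VH", "VL", "VL"),
                        primer = c("AGACAGATGGGGGT", "GATGGTGGGAAGAT",
                                   "CCTTGGGAAGATGG"),
                        stringsAsFactors = FALSE)
  body <- strrep("ACGT", 10)
  r <- read_df(paste0(body, "AGACAGATGGGGGT"))
  a <- assign_chain_and_excise(r, primers, max_mismatches = 2)
  expect_equal(a$reads$chain, "VH")
  expect_equal(a$reads$seq, body)

  # matches the second VL cocktail primer
  r2 <- read_df(paste0(body, "CCTTGGGAAGATGG"))
  expect_equal(assign_chain_and_excise(r2, primers)$reads$chain, "VL")

  # equally good match to a VH and a VL primer -> ambiguous, discarded
  p_tie <- data.frame(chain = c("VH", "VL"),
                      primer = c("AAAACCCCGGGGTT", "AAAACCCCGGGGTA"),
                      stringsAsFactors = FALSE)
  r3 <- read_df(paste0(body, "AAAACCCCGGGGTC"))
  a3 <- assign_chain_and_excise(r3, p_tie, max_mismatches = 2)
  expect_equal(nrow(a3$reads), 0L)
  expect_equal(nrow(a3$discarded), 1L)

  expect_error(assign_chain_and_excise(r, primers[0, ]), "empty primer table")
})

test_that("TSO removal tolerates mismatches and leaves other reads alone", {
  tso <- "AAGCAGTGGTAT"
  body <- strrep("GC", 20)
  r <- read_df(c(paste0(tso, body),                      # exact
                 paste0("AAGCAGTGGTAA", body),           # 1 mismatch
                 paste0("TTTTTTTTTTTT", body)))          # no TSO
  out <- remove_tso(r, tso, max_mismatches = 1)
  expect_equal(out$reads$seq[1], body)
  expect_equal(out$reads$seq[2], body)
  expect_equal(out$reads$seq[3], paste0("TTTTTTTTTTTT", body))
  expect_equal(out$log$reads_discarded, 0L)
})

test_that("N filtering and quality trimming follow the stated rules", {
  f <- filter_n(read_df(c("ACGT", "ACNT", "NNNN")))
  expect_equal(f$reads$seq, "ACGT")
  expect_equal(nrow(f$discarded), 2L)

  q <- quality_trim_3prime(read_df("ACGTA", qstr(c(30, 30, 30, 9, 8))))
  expect_equal(q$reads$seq, "ACG")
  expect_equal(nchar(q$reads$qual), 3L)
  q2 <- quality_trim_3prime(read_df("ACGTA", qstr(rep(10, 5))))
  expect_equal(q2$reads$seq, "ACGTA")
  q3 <- quality_trim_3prime(read_df("ACGTA", qstr(rep(9, 5))))
  expect_equal(q3$reads$seq, "")
})

test_that("length filter boundary sits exactly at the minimum", {
  reads <- read_df(c(strrep("A", 384), strrep("C", 385), strrep("G", 500)))
  lf <- length_filter(reads, min_len = 385)
  expect_equal(nchar(lf$reads$seq), c(385L, 500L))
  expect_equal(nrow(lf$discarded), 1L)
})

test_that("every cascade stage conserves reads and error-free data loses none", {
  run <- clean_run()
  p <- run$plates[[1]]
  st <- process_reads(p$r1, p$r2, p$sample_sheet[, c("well_id", "barcode")],
                      run$primer_set, run$tso)
  expect_true(all(st$log$reads_in ==
                  st$log$reads_out + st$log$reads_discarded))
  expect_equal(st$log$reads_in[1], nrow(p$r1))
  expect_equal(sum(st$log$reads_discarded), 0L)
  expect_equal(nrow(st$reads), nrow(p$r1))
})

test_that("demultiplexing at zero mismatches partitions the reads", {
  run <- noisy_run()
  p <- run$plates[[1]]
  m <- merge_pairs(p$r1, p$r2)
  d <- demultiplex(m$reads, p$sample_sheet[, c("well_id", "barcode")], 0)
  expect_equal(nrow(d$reads) + nrow(d$unassigned), nrow(m$reads))
  expect_equal(anyDuplicated(d$reads$id), 0L)
})
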