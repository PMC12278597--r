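test_that("best-frame translation finds shifted ORFs and rejects stop-ridden input", {
  cl <- generate_clone(3)
  nt <- cl$chains$VL$nt
  tr <- translate_best_frame(nt)
  expect_equal(tr$frame, cl$chains$VL$frame)
  # shifting by one base moves the frame accordingly
  tr1 <- translate_best_frame(paste0("G", nt))
  expect_equal(tr1$frame, (cl$chains$VL$frame + 1L) %% 3L)
  # the 4-periodic TAAC repeat carries stop codons in all three frames
  expect_null(translate_best_frame(strrep("TAAC", 120)))
})

test_that("the table annotator reproduces truth regions and handles TCR chains", {
  cl <- generate_clone(6, c("VL", "VH", "beta"))
  tab <- clone_region_table(list(cl))
  ann <- annotator("table", regions = tab)
  for (cc in c("VL", "VH", "beta")) {
    ch <- cl$chains[[cc]]
    aa_full <- platevdj:::translate_nt(substring(ch$nt, ch$frame + 1))
    got <- annotate(aa_full, ann, nt = ch$nt, frame = ch$frame)
    expect_false(is.null(got))
    expect_equal(got$chain_class, cc)
    expect_equal(unlist(got$regions), ch$regions)
  }
  # a non-immunoglobulin amino-acid string finds no home
  expect_null(annotate(strrep("PQRS", 40), ann))
  expect_error(annotator("anarci"), "unknown annotator backend")
  expect_error(annotator("table"), "region table")
})

test_that("the motif annotator anchors on conserved cysteines and the J motif", {
  mot <- annotator("motif")
  annotated <- 0L; class_ok <- 0L; cdr3_ok <- 0L; total <- 0L
  for (s in 1:10) {
    cl <- generate_clone(s)
    for (cc in c("VL", "VH")) {
      total <- total + 1L
      ch <- cl$chains[[cc]]
      aa_full <- platevdj:::translate_nt(substring(ch$nt, ch$frame + 1))
      got <- annotate(aa_full, mot, nt = ch$nt, frame = ch$frame)
      if (!is.null(got)) {
        annotated <- annotated + 1L
        class_ok <- class_ok + (got$chain_class == cc)
        cdr3_ok <- cdr3_ok +
          identical(unlist(got$regions)[["CDR3"]], ch$regions[["CDR3"]])
      }
    }
  }
  # a heuristic, not an aligner: it must place most clean chains, never
  # mistake the chain class, and usually pin the CDR3 exactly
  expect_gte(annotated, as.integer(0.75 * total))
  expect_equal(class_ok, annotated)
  expect_gte(cdr3_ok, as.integer(0.6 * annotated))
  # random junk is rejected rather than force-fitted
  expect_null(annotate(paste(rep("ELVISLIVES", 15), collapse = ""), mot))
})

test_that("zero-length regions are filtered out", {
  regs <- c(FR1 = "AAAA", CDR1 = "GG", FR2 = "SSS", CDR2 = "TT",
            FR3 = "VVVV", CDR3 = "WW", FR4 = "FFFF")
  good <- manual_chain("VL", regs, seq_len(sum(nchar(regs))),
                       strrep("ACT", sum(nchar(regs))))
  expect_true(filter_zero_length_regions(good))
  for (r in c("CDR2", "FR4")) {
    bad_regs <- regs
    bad_regs[r] <- ""
    bad <- manual_chain("VL", bad_regs, seq_len(sum(nchar(bad_regs))),
                        strrep("ACT", sum(nchar(bad_regs))))
    expect_false(filter_zero_length_regions(bad))
  }
})

test_that("amino-acid binning merges synonymous/trailing variants and conserves reads", {
  run <- clean_run()
  cl <- run$clones[[1]]
  ann <- annotator("table", regions = run$clone_regions)
  nt <- cl$chains$VH$nt
  asv <- data.frame(plate = "p1", well = "A1", sample_id = "A/1.1",
                    chain = "VH",
                    seq = c(nt, paste0(nt, "ACGTAC")),  # differs 3' of FR4
                    count = c(30L, 10L), support_fraction = c(0.75, 0.25),
                    stringsAsFactors = FALSE)
  annd <- annotate_asvs(asv, ann)
  expect_equal(nrow(annd), 2L)
  bins <- bin_by_aa(annd)
  expect_equal(nrow(bins), 1L)
  expect_equal(bins$total_count, 40L)
  expect_equal(bins$representative_nt, nt)

  # different CDR3 -> different bins
  other <- run$clones[[2]]$chains$VH$nt
  asv2 <- rbind(asv[1, ],
                within(asv[1, ], { seq <- other; count <- 5L }))
  bins2 <- bin_by_aa(annotate_asvs(asv2, ann))
  expect_equal(nrow(bins2), 2L)
  expect_equal(sum(bins2$total_count), sum(asv2$count))

  # single ASV -> single bin carrying its count
  bins3 <- bin_by_aa(annotate_asvs(asv[1, ], ann))
  expect_equal(bins3$total_count, 30L)
})

test_that("the support filter keeps bins at or above the inclusive minimum", {
  bins <- data.frame(plate = "p1", well = "A1", sample_id = "S/1",
                     chain_class = "VL", aa_vdomain = c("a", "b", "c"),
                     total_count = c(60L, 30L, 8L), stringsAsFactors = FALSE)
  totals <- data.frame(plate = "p1", well = "A1", chain = "VL",
                       total_reads = 100L, stringsAsFactors = FALSE)
  kept <- asv_support_filter(bins, totals, min_support = 0.10)
  expect_equal(kept$aa_vdomain, c("a", "b"))

  bins$total_count <- c(10L, 90L, 0L)   # exactly 10% is retained
  kept2 <- asv_support_filter(bins[1:2, ], totals, min_support = 0.10)
  expect_equal(nrow(kept2), 2L)

  one <- asv_support_filter(
    data.frame(plate = "p1", well = "A1", sample_id = "S/1",
               chain_class = "VL", aa_vdomain = "a", total_count = 100L,
               stringsAsFactors = FALSE), totals, 0.10)
  expect_equal(one$support, 1)
})

test_that("reported spans cover IMGT 1-127 (light) and 1-128 (heavy) when complete", {
  for (s in 4:8) {
    cl <- generate_clone(s)
    tab <- clone_region_table(list(cl))
    ann <- annotator("table", regions = tab)
    for (cc in c("VL", "VH")) {
      ch <- cl$chains[[cc]]
      aa_full <- platevdj:::translate_nt(substring(ch$nt, ch$frame + 1))
      got <- annotate(aa_full, ann, nt = ch$nt, frame = ch$frame)
      expect_equal(min(got$imgt_positions), 1L)
      expect_equal(max(got$imgt_positions), if (cc == "VL") 127L else 128L)
      expect_equal(nchar(got$nt_reported), 3L * nchar(ch$aa))
      expect_equal(platevdj:::translate_nt(got$nt_reported), ch$aa)
    }
  }
})

test_that("a chain missing leading IMGT positions narrows its span without padding", {
  regs <- c(FR1 = "AAAA", CDR1 = "GG", FR2 = "SSS", CDR2 = "TT",
            FR3 = "VVVV", CDR3 = "WW", FR4 = "FFFF")
  n <- sum(nchar(regs))
  nt <- strrep("GCT", n)
  ch <- manual_chain("VL", regs, imgt_positions = seq(3L, 2L + n),
                     nt_vdomain = nt)
  got <- extract_reported_nt(ch)
  expect_equal(got, nt)           # span starts at position 3's codon: no padding
  # positions beyond the light-chain cap are excluded
  ch2 <- manual_chain("VL", regs, imgt_positions = seq(120L, 119L + n),
                      nt_vdomain = nt)
  got2 <- extract_reported_nt(ch2)
  expect_equal(nchar(got2), 3L * (127L - 120L + 1L))
})

test_that("annotation of a kept chain is idempotent", {
  res <- clean_results()
  run <- clean_run()
  ann <- annotator("table", regions = run$clone_regions)
  bins <- res$bins
  for (i in seq_len(min(4, nrow(bins)))) {
    re <- annotate(bins$aa_vdomain[i], ann)
    expect_false(is.null(re))
    expect_equal(paste(unlist(re$regions), collapse = ""), bins$aa_vdomain[i])
    expect_equal(unlist(re$regions),
                 setNames(unlist(bins[i, platevdj:::REGION_NAMES]),
                          platevdj:::REGION_NAMES))
  }
})

test_that("on error-free data every retained bin matches a truth sequence", {
  res <- clean_results()
  run <- clean_run()
  expect_true(all(res$bins$representative_nt %in% run$truth$sequence))
  # binning conserves annotated reads
  expect_equal(sum(bin_by_aa(res$annotated)$total_count),
               sum(res$annotated$count))
})
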