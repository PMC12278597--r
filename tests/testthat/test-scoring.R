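test_that("sample IDs parse on the first slash and last dot", {
  p <- parse_sample_id("L130/1.1")
  expect_equal(p[c("project", "parent", "subclone")],
               list(project = "L130", parent = "1", subclone = "1"))
  p2 <- parse_sample_id("N158/28")
  expect_equal(p2$parent, "28")
  expect_true(is.na(p2$subclone))
  p3 <- parse_sample_id("X/Y.Z.W")
  expect_equal(p3$parent, "Y.Z")
  expect_equal(p3$subclone, "W")
  expect_error(parse_sample_id("noslash"), "missing '/'.*noslash")
})

test_that("replicate counting separates biological from technical support", {
  # all three subclones of a parent support the bin
  rc <- count_replicates(c("1", "2", "3"), 3)
  expect_equal(rc, list(br = 3L, tr = 0L, total_replicates = 3L))
  # two samples of subclone 1 plus subclones 2 and 3, in a group of 6
  rc2 <- count_replicates(c("1", "1", "2", "3"), 6)
  expect_equal(rc2, list(br = 3L, tr = 1L, total_replicates = 6L))
  rc3 <- count_replicates("1", 3)
  expect_equal(rc3$br, 1L)
  expect_equal(rc3$tr, 0L)
  # absent subclone parts behave as one shared subclone
  rc4 <- count_replicates(c(NA, NA), 2)
  expect_equal(rc4, list(br = 1L, tr = 1L, total_replicates = 2L))
  expect_error(count_replicates(c("1", "2"), 1), "more supporting")
})

test_that("asv_score is the read-support ratio with guarded preconditions", {
  expect_equal(asv_score(300, 1000), 0.3)
  expect_equal(asv_score(1000, 1000), 1)
  expect_equal(asv_score(0, 1000), 0)
  expect_error(asv_score(10, 0))
  expect_error(asv_score(1001, 1000))
})

test_that("match_score follows the replicate formula", {
  expect_equal(match_score(5, 0, 5, 1), 5)
  expect_equal(match_score(2, 2, 8, 0.5), 2.5)
  expect_equal(match_score(1, 0, 1, 1), 1)
  # can go non-positive for a lone hit in a large group
  expect_lt(match_score(1, 0, 100, 1), 1)
  expect_error(match_score(3, 3, 4, 1))
})

test_that("total_score clamps the match component and honours the literal mode", {
  p <- scoring_params()
  expect_equal(total_score(exp(3), 1, p), 5)
  expect_equal(total_score(5, 1, p), log(5) + 2)
  expect_equal(total_score(1, 0, p), 0)
  expect_equal(total_score(0, 0.5, p), 1)      # non-positive match -> 0 + mu*asv
  expect_equal(total_score(-2, 0, p), 0)
  lit <- scoring_params(literal_max = TRUE)
  expect_equal(total_score(exp(4), 0, lit), 4)  # literal max() exceeds the ceiling
  expect_equal(total_score(exp(4), 0, p), 3)    # default mode clamps at lam
  expect_equal(total_score(1, 0, lit), 3)       # literal mode cannot go below lam
})

test_that("scoring parameter validation enforces the published constraints", {
  expect_error(scoring_params(mu = 3, lam = 3), "mu \\+ lam")
  expect_error(scoring_params(nu = 1.5), "nu")
  p <- scoring_params(mu = 1, lam = 4)
  expect_equal(p$lam, 4)
})

test_that("match_score is monotone in BR and nu behaves as documented", {
  for (total in c(4, 8, 12)) {
    for (tr in 0:2) {
      brs <- seq_len(total - tr)
      ms <- vapply(brs, match_score, numeric(1), tr = tr,
                   total_replicates = total, nu = 1)
      expect_true(all(diff(ms) > 0))
    }
  }
  # nu = 1: a TR counts like a BR in the reward term
  expect_equal(match_score(2, 2, 6, 1), match_score(4, 0, 6, 1))
  # nu = 0: TRs add no reward but still shrink the coverage penalty
  expect_equal(match_score(2, 2, 8, 0), 2 - (1 - 4 / 8))
  expect_gt(match_score(2, 2, 8, 0), match_score(2, 0, 8, 0))
})

test_that("default-mode total scores stay inside [0, 5] over a replicate grid", {
  p <- scoring_params()
  for (total in 1:12) for (br in 0:total) for (tr in 0:(total - br)) {
    if (br + tr == 0) next
    m <- match_score(max(br, 0), tr, total, 1)
    for (asv in c(0, 0.3, 1)) {
      s <- total_score(m, asv, p)
      expect_gte(s, 0)
      expect_lte(s, 5)
    }
  }
})

test_that("aberrant light chains are flagged strictly above 50% prevalence", {
  mk <- function(n_with, n_total, chain = "VL") {
    data.frame(plate = "p1", well = sprintf("W%d", seq_len(n_total)),
               chain_class = c(rep(chain, n_with),
                               rep("VH", n_total - n_with)),
               aa_vdomain = c(rep("QQ", n_with),
                              sprintf("h%d", seq_len(n_total - n_with))),
               stringsAsFactors = FALSE)
  }
  expect_true(any(remove_aberrant_light_chains(mk(6, 10))$aberrant_flag))
  expect_false(any(remove_aberrant_light_chains(mk(5, 10))$aberrant_flag))
  # heavy chains are never flagged, however prevalent
  vh <- mk(9, 10, chain = "VH")
  expect_false(any(remove_aberrant_light_chains(vh)$aberrant_flag))
})

test_that("complexity multiplies distinct light and heavy counts", {
  e <- data.frame(chain_class = c("VL", "VL", "VH", "VH", "VH"),
                  aa_vdomain = c("l1", "l2", "h1", "h2", "h3"),
                  stringsAsFactors = FALSE)
  expect_equal(complexity(e), 6L)
  expect_equal(complexity(e[c(1, 3), ]), 1L)
  expect_equal(complexity(e[1:2, ]), 0L)
})

test_that("percentiles use the strictly-below convention", {
  pop <- c(1, 2, 3, 4, 5)
  expect_equal(score_percentile(5, pop), 4 / 5)
  expect_equal(score_percentile(1, pop), 0)
  expect_equal(score_percentile(3.5, 3.5), 0)
})

test_that("high-confidence pair selection applies threshold, maximum, and uniqueness", {
  p <- scoring_params()
  s1 <- rbind(fake_scored("P/1.1", "VL", "lightA", 4.5),
              fake_scored("P/1.1", "VH", "heavyA", 4.2))
  expect_equal(nrow(select_high_confidence_pairs(s1, p)), 1L)

  # strictly greater than 4: a 4.0 chain does not qualify
  s2 <- rbind(fake_scored("P/1.1", "VL", "lightA", 4.0),
              fake_scored("P/1.1", "VH", "heavyA", 4.2))
  expect_equal(nrow(select_high_confidence_pairs(s2, p)), 0L)

  # several qualifying light chains: the maximum-scoring one is kept
  s3 <- rbind(fake_scored("P/1.1", "VL", "lightA", 4.3),
              fake_scored("P/1.1", "VL", "lightB", 4.8),
              fake_scored("P/1.1", "VH", "heavyA", 4.2))
  expect_equal(select_high_confidence_pairs(s3, p)$light_aa, "lightB")

  # two parent lines sharing a light chain: both pairs dropped
  s4 <- rbind(fake_scored("P/1.1", "VL", "sharedL", 4.5),
              fake_scored("P/1.1", "VH", "heavyA", 4.5),
              fake_scored("Q/2.1", "VL", "sharedL", 4.6),
              fake_scored("Q/2.1", "VH", "heavyB", 4.6))
  expect_equal(nrow(select_high_confidence_pairs(s4, p)), 0L)

  # verified-by-cloning entries qualify regardless of score
  s5 <- rbind(fake_scored("P/1.1", "VL", "lightA", 2.0, verified = TRUE),
              fake_scored("P/1.1", "VH", "heavyA", 4.2))
  expect_equal(nrow(select_high_confidence_pairs(s5, p)), 1L)

  # aberrant-flagged chains never pair
  s6 <- rbind(fake_scored("P/1.1", "VL", "lightA", 4.9, aberrant = TRUE),
              fake_scored("P/1.1", "VH", "heavyA", 4.2))
  expect_equal(nrow(select_high_confidence_pairs(s6, p)), 0L)
})

test_that("subclones of one parent keep their shared chains pairable", {
  p <- scoring_params()
  s <- rbind(fake_scored(c("P/1.1", "P/1.2"), "VL", "sameL", 4.5),
             fake_scored(c("P/1.1", "P/1.2"), "VH", "sameH", 4.5))
  got <- select_high_confidence_pairs(s, p)
  expect_equal(nrow(got), 2L)
})

test_that("BR-consistent parents outscore BR-mismatched ones, and TRs downgrade", {
  p <- scoring_params()
  # parent with 5 matching BRs vs the same support split 2 BR + mismatches
  full <- total_score(match_score(5, 0, 5, 1), 0.8, p)
  partial <- total_score(match_score(2, 0, 5, 1), 0.8, p)
  expect_gt(full, partial)
  # converting BR matches to TR matches lowers the score when nu < 1
  p_half <- scoring_params(nu = 0.5)
  br_heavy <- total_score(match_score(4, 0, 5, 0.5), 0.8, p_half)
  tr_heavy <- total_score(match_score(1, 3, 5, 0.5), 0.8, p_half)
  expect_gt(br_heavy, tr_heavy)
})

test_that("score_run integrates replicate counting over a synthetic run", {
  res <- clean_results()
  sc <- res$scored
  # every parent has 3 subclone wells and consistent chains: br = 3
  expect_true(all(sc$br == 3L))
  expect_true(all(sc$tr == 0L))
  expect_true(all(sc$total_replicates == 3L))
  expect_true(all(abs(sc$match_score - 3) < 1e-12))
  expect_true(all(sc$asv_score == 1))
  expect_equal(unique(round(sc$total_score, 6)), round(log(3) + 2, 6))
  expect_false(any(sc$aberrant_flag))
})
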