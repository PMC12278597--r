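# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Small error-free run: 2 parents x 3 subclones, 1 plate, no aberrant chain.
clean_run <- function() cached("clean_run", function() {
  generate_run(c("A/1" = 3, "B/2" = 3), n_plates = 1, aberrant_chain = NULL,
               reads_per_well = 60, error_rate = 0, seed = 11)
})

clean_results <- function() cached("clean_results", function() {
  run <- clean_run()
  ann <- annotator("table", regions = run$clone_regions)
  process_run(run$plates, run$primer_set, run$tso, ann)
})

# Realistic run: 8 parents x 3 biological replicates over 2 plates, the
# aberrant light chain spiked into 60% of samples, substitution errors.
noisy_run <- function() cached("noisy_run", function() {
  generate_run(c("A/1" = 3, "A/2" = 3, "B/3" = 3, "B/4" = 3, "C/5" = 3,
                 "C/6" = 3, "D/7" = 3, "D/8" = 3),
               n_plates = 2, aberrant_chain = TRUE,
               aberrant_prevalence = 0.6, reads_per_well = 200,
               error_rate = 0.002, seed = 7)
})

noisy_results <- function() cached("noisy_results", function() {
  run <- noisy_run()
  ann <- annotator("table", regions = run$clone_regions)
  process_run(run$plates, run$primer_set, run$tso, ann)
})

# Quality string from integer Phred scores.
qstr <- function(q) intToUtf8(q + 33L)

read_df <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- vapply(nchar(seqs), function(n)
    qstr(rep(30L, n)), character(1))
  data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

# Minimal scored-table fixture for scoring/pair-selection tests.
fake_scored <- function(sample_id, chain_class, aa, score,
                        asv = 0.9, aberrant = FALSE, verified = FALSE,
                        nt = NULL) {
  data.frame(plate = "p1", well = paste0("W", seq_along(sample_id)),
             sample_id = sample_id, chain_class = chain_class,
             aa_vdomain = aa,
             nt_reported = nt %||% vapply(aa, function(a)
               paste(rep("ACT", nchar(a)), collapse = ""), character(1)),
             total_score = score, asv_score = asv,
             aberrant_flag = aberrant, verified = verified,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, code) platevdj:::with_seed(seed, code)

# One side of a pair candidate with a chosen CDR3 length.
make_side <- function(chain_class, cdr3_len, total_pad = 2) {
  regions <- setNames(c(strrep("A", 25), strrep("G", 8), strrep("S", 17),
                        strrep("T", 8), strrep("V", 36),
                        strrep("Y", cdr3_len), strrep("F", 10 + total_pad)),
                      platevdj:::REGION_NAMES)
  list(chain_class = chain_class, regions = as.list(regions))
}

# Separable candidate set: true pairs have matching planted CDR3 lengths,
# scrambled pairs break the correlation.
separable_candidates <- function(n = 40, seed = 20) {
  with_seed(seed, {
    # scramble partners (adjacent indices) always get distinct lengths, so
    # the planted CDR3-length covariate fully separates the classes
    lens <- ifelse(seq_len(n) %% 2 == 1, sample(5:8, n, replace = TRUE),
                   sample(10:13, n, replace = TRUE))
    pos <- lapply(seq_len(n), function(i)
      list(l = make_side("VL", lens[i]), h = make_side("VH", lens[i] + 2),
           la = paste0("L", i, strrep("A", lens[i])),
           ha = paste0("H", i, strrep("A", lens[i]))))
    # adjacent transpositions: valid derangement, small chain-sharing groups
    perm <- as.vector(rbind(seq(2, n, by = 2), seq(1, n - 1, by = 2)))
    rows <- lapply(seq_len(n), function(i) {
      f_pos <- featurize_pair(pos[[i]]$l, pos[[i]]$h)
      f_neg <- featurize_pair(pos[[i]]$l, pos[[perm[i]]]$h)
      rbind(cbind(data.frame(label = 1L, light_aa = pos[[i]]$la,
                             heavy_aa = pos[[i]]$ha,
                             stringsAsFactors = FALSE),
                  as.data.frame(as.list(f_pos))),
            cbind(data.frame(label = 0L, light_aa = pos[[i]]$la,
                             heavy_aa = pos[[perm[i]]]$ha,
                             stringsAsFactors = FALSE),
                  as.data.frame(as.list(f_neg))))
    })
    do.call(rbind, rows)
  })
}

# A manually built annotated_chain (for span-narrowing tests).
manual_chain <- function(chain_class, regions, imgt_positions, nt_vdomain) {
  structure(list(aa_seq = paste(regions, collapse = ""),
                 chain_class = chain_class, regions = as.list(regions),
                 imgt_positions = imgt_positions, v_start_aa = 1L,
                 frame = 0L, nt_vdomain = nt_vdomain,
                 nt_reported = NA_character_),
            class = "annotated_chain")
}
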