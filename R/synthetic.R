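# Synthetic plate simulator: clones, plates and whole runs with known ground
# truth, emulating the well-barcoded, TSO/constant-primer amplicon library
# structure the processing cascade assumes.

DEFAULT_TSO <- "AAGCAGTGGTATCAACGCAGAGTACATGGG"

DEFAULT_PRIMERS <- c(
  VL    = "GATGGTGGGAAGATGGATACAG",
  VH    = "AGACAGATGGGGGTGTCGTTTT",
  alpha = "GGGTCAGGGTTCTGGATATCTG",
  beta  = "TGGCTCAAACACAGCGACCTCG",
  gamma = "CTTCTGGAATGTGTCAGGTGGG",
  delta = "CTTGGGGTAGAAATCTTTCCAG"
)

# FR4 amino-acid sequences per chain class: 10 residues for light-type
# chains (IMGT 118-127), 11 for heavy-type (118-128). The leading [FW]G.G
# J-motif is what the motif annotator anchors on.
FR4_AA <- c(
  VL = "FGGGTKLTVL",  alpha = "FGKGTKLSVL", gamma = "FGSGTKLIVT",
  VH = "WGQGTLVTVSS", beta = "FGQGTRLTVLE", delta = "FGEGTQLIVEP"
)

#' Generate a synthetic clone
#'
#' Draws a clonal cell line's variable-domain sequences: one chain per
#' requested class, each built from random non-stop codons with the
#' conserved FR1/FR3 cysteines and an FR4 J-motif planted so motif-based
#' annotation has anchors. The nucleotide sequence per chain is the full
#' insert the pipeline recovers after barcode/TSO/primer excision: a 5'
#' leader, the variable domain, and a short constant-region stub, always at
#' least 385 nt so reads survive the minimum-length filter.
#'
#' @param seed non-negative integer; the generator is deterministic per seed.
#' @param chain_classes character vector of chain classes to emit
#'   (default `c("VL","VH")`).
#' @return A `clone_spec`: list with `clone_id`, `seed`, and `chains`, a
#'   named list with per-chain `nt` (insert), `v_start` (1-based nt offset
#'   of the variable domain), `frame` (0/1/2), `aa` (variable-domain amino
#'   acids) and `regions` (named FR/CDR amino-acid segments).
#' @export
generate_clone <- function(seed, chain_classes = c("VL", "VH")) {
  stopifnot(length(seed) == 1L, is.finite(seed), seed >= 0, seed == floor(seed))
  if (!all(chain_classes %in% CHAIN_CLASSES))
    stop("unknown chain class: ", paste(setdiff(chain_classes, CHAIN_CLASSES), collapse = ", "))
  with_seed(seed, {
    chains <- lapply(chain_classes, function(cc) .generate_chain(cc))
    names(chains) <- chain_classes
    structure(list(clone_id = sprintf("C%d", as.integer(seed)),
                   seed = as.integer(seed), chains = chains),
              class = "clone_spec")
  })
}

.generate_chain <- function(chain_class) {
  len <- c(FR1 = sample(24:26, 1L), CDR1 = sample(6:12, 1L),
           FR2 = sample(16:17, 1L), CDR2 = sample(4:10, 1L),
           FR3 = sample(36:39, 1L), CDR3 = sample(5:13, 1L),
           FR4 = nchar(FR4_AA[[chain_class]]))
  nt <- list(
    FR1  = .plant(random_codons(len[["FR1"]]), 23L, "C"),
    CDR1 = random_codons(len[["CDR1"]]),
    FR2  = random_codons(len[["FR2"]]),
    CDR2 = random_codons(len[["CDR2"]]),
    FR3  = .plant(random_codons(len[["FR3"]]), len[["FR3"]], "C"),
    CDR3 = random_codons(len[["CDR3"]]),
    FR4  = aa_to_nt(FR4_AA[[chain_class]])
  )
  regions <- vapply(nt, translate_nt, character(1))
  vd_nt <- paste(unlist(nt), collapse = "")
  aa_len <- sum(len)

  frame <- sample(0:2, 1L)
  n_leader <- min(max(16L, as.integer(ceiling((371L - 3L * aa_len) / 3))) + sample(0:4, 1L),
                  (431L - 3L * aa_len) %/% 3L)
  leader <- paste0(random_dna(frame), random_codons(n_leader))
  stub <- random_codons(7L)
  insert <- paste0(leader, vd_nt, stub)

  list(chain_class = chain_class, nt = insert,
       v_start = nchar(leader) + 1L, frame = frame,
       aa = paste(regions, collapse = ""), regions = regions,
       region_lengths = len)
}

.plant <- function(codons, aa_pos, aa) {
  substr(codons, 3L * (aa_pos - 1L) + 1L, 3L * aa_pos) <- AA_CODON[[aa]]
  codons
}

#' Construct a plate specification
#'
#' @param plate_id plate label.
#' @param wells data.frame with columns `well_id`, `sample_id`, `barcode`.
#' @param well_clones data.frame with columns `well_id`, `clone_id`,
#'   `chain`, `fraction`: the within-chain mixture of each well. Fractions
#'   must sum to 1 per well and chain.
#' @param primer_set named character vector, chain class -> constant-region
#'   primer sequence.
#' @param tso template-switch oligo sequence.
#' @param error_rate substitution probability per sequenced base.
#' @param reads_per_well read pairs simulated per well (> 0).
#' @param read_len length of each mate.
#' @param seed RNG seed for the plate.
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(plate_id, wells, well_clones,
                       primer_set = DEFAULT_PRIMERS[c("VL", "VH")],
                       tso = DEFAULT_TSO, error_rate = 0.002,
                       reads_per_well = 200L, read_len = 300L, seed = 1L) {
  stopifnot(is.data.frame(wells),
            all(c("well_id", "sample_id", "barcode") %in% names(wells)),
            all(c("well_id", "clone_id", "chain", "fraction") %in% names(well_clones)))
  if (anyDuplicated(wells$barcode))
    stop("barcodes must be unique within a plate")
  if (reads_per_well <= 0L) stop("reads_per_well must be > 0")
  sums <- tapply(well_clones$fraction,
                 paste(well_clones$well_id, well_clones$chain), sum)
  if (any(abs(sums - 1) > 1e-8))
    stop("mixture fractions must sum to 1 per well and chain")
  structure(list(plate_id = plate_id, wells = wells, well_clones = well_clones,
                 primer_set = primer_set, tso = tso, error_rate = error_rate,
                 reads_per_well = as.integer(reads_per_well),
                 read_len = as.integer(read_len), seed = as.integer(seed)),
            class = "plate_spec")
}

# Largest-remainder apportionment of n among weights w (deterministic).
.apportion <- function(n, w) {
  raw <- n * w / sum(w)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(raw - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1
  }
  as.integer(k)
}

# Per-position mean quality: q37 flat with a linear decay to q8 over the
# final 30 positions, so the q<10 3'-trim rule is exercised on raw reads.
quality_profile <- function(read_len, q_high = 37L, q_low = 8L, decay_len = 30L) {
  decay_len <- min(decay_len, read_len)
  q <- rep(q_high, read_len)
  if (decay_len > 0L)
    q[(read_len - decay_len + 1L):read_len] <-
      as.integer(round(seq(q_high, q_low, length.out = decay_len)))
  q
}

#' Simulate one plate of paired-end reads
#'
#' Builds the full amplicon for every well/chain/clone combination
#' (barcode + TSO + insert + constant primer), slices `read_len` bases from
#' each end, applies substitution errors and the 3'-decaying quality
#' profile, and returns the read pairs with a ground-truth table. Output is
#' byte-deterministic for a fixed spec.
#'
#' @param plate a [plate_spec()].
#' @param clones list of `clone_spec` objects covering every `clone_id`
#'   referenced by the plate.
#' @param outdir optional directory; when given, R1/R2 FASTQ (gzipped),
#'   the sample sheet, barcode table, primer FASTA and truth table are
#'   written there.
#' @return List with `r1`/`r2` read data.frames (`id`, `seq`, `qual`),
#'   `sample_sheet`, `truth` (well_id, sample_id, chain, clone_id,
#'   sequence, fraction) and `files` (paths, when written).
#' @export
generate_plate <- function(plate, clones, outdir = NULL) {
  stopifnot(inherits(plate, "plate_spec"))
  clone_ids <- vapply(clones, `[[`, "", "clone_id")
  names(clones) <- clone_ids
  missing <- setdiff(plate$well_clones$clone_id, clone_ids)
  if (length(missing)) {
    w <- plate$well_clones$well_id[match(missing[1], plate$well_clones$clone_id)]
    stop(sprintf("unknown clone_id '%s' referenced by well %s", missing[1], w))
  }

  qprof <- quality_profile(plate$read_len)
  qstr <- intToUtf8(qprof + 33L)

  with_seed(plate$seed, {
    ids <- seqs1 <- seqs2 <- character(0)
    truth <- list()
    for (wi in seq_len(nrow(plate$wells))) {
      well <- plate$wells[wi, ]
      wc <- plate$well_clones[plate$well_clones$well_id == well$well_id, , drop = FALSE]
      wc <- wc[order(wc$chain, wc$clone_id), , drop = FALSE]
      chains_here <- unique(wc$chain)
      n_chain <- .apportion(plate$reads_per_well, rep(1, length(chains_here)))
      for (ci in seq_along(chains_here)) {
        ch <- chains_here[ci]
        sub <- wc[wc$chain == ch, , drop = FALSE]
        n_clone <- .apportion(n_chain[ci], sub$fraction)
        for (k in seq_len(nrow(sub))) {
          if (n_clone[k] == 0L) next
          cl <- clones[[sub$clone_id[k]]]
          insert <- cl$chains[[ch]]$nt
          amp <- paste0(well$barcode, plate$tso, insert, plate$primer_set[[ch]])
          L <- nchar(amp)
          r1 <- substr(amp, 1L, plate$read_len)
          r2 <- revcomp(substr(amp, L - plate$read_len + 1L, L))
          n <- n_clone[k]
          s1 <- .add_substitutions(rep(r1, n), plate$error_rate)
          s2 <- .add_substitutions(rep(r2, n), plate$error_rate)
          idx <- length(ids) + seq_len(n)
          ids <- c(ids, sprintf("%s:%06d %s:%s", plate$plate_id, idx,
                                well$well_id, ch))
          seqs1 <- c(seqs1, s1)
          seqs2 <- c(seqs2, s2)
        }
      }
      for (k in seq_len(nrow(wc)))
        truth[[length(truth) + 1L]] <- data.frame(
          well_id = well$well_id, sample_id = well$sample_id,
          chain = wc$chain[k], clone_id = wc$clone_id[k],
          sequence = clones[[wc$clone_id[k]]]$chains[[wc$chain[k]]]$nt,
          fraction = wc$fraction[k], stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    out <- list(plate_id = plate$plate_id,
                r1 = data.frame(id = ids, seq = seqs1, qual = qstr,
                                stringsAsFactors = FALSE),
                r2 = data.frame(id = ids, seq = seqs2, qual = qstr,
                                stringsAsFactors = FALSE),
                sample_sheet = data.frame(plate_id = plate$plate_id,
                                          well_id = plate$wells$well_id,
                                          sample_id = plate$wells$sample_id,
                                          barcode = plate$wells$barcode,
                                          stringsAsFactors = FALSE),
                truth = truth, spec = plate)
    if (!is.null(outdir)) out$files <- .write_plate(out, outdir)
    out
  })
}

.add_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

.write_plate <- function(plate_out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pid <- plate_out$plate_id
  f <- list(
    r1 = file.path(outdir, paste0(pid, "_R1.fastq.gz")),
    r2 = file.path(outdir, paste0(pid, "_R2.fastq.gz")),
    sample_sheet = file.path(outdir, paste0(pid, "_samples.csv")),
    barcodes = file.path(outdir, paste0(pid, "_barcodes.tsv")),
    primers = file.path(outdir, paste0(pid, "_primers.fasta")),
    truth = file.path(outdir, paste0(pid, "_truth.tsv"))
  )
  write_fastq(plate_out$r1, f$r1)
  write_fastq(plate_out$r2, f$r2)
  utils::write.csv(plate_out$sample_sheet, f$sample_sheet, row.names = FALSE,
                   quote = FALSE)
  write.table(plate_out$sample_sheet[, c("well_id", "barcode")], f$barcodes,
              sep = "\t", row.names = FALSE, quote = FALSE)
  write_primer_fasta(plate_out$spec$primer_set, f$primers)
  write.table(plate_out$truth, f$truth, sep = "\t", row.names = FALSE,
              quote = FALSE)
  f
}

.normalize_design <- function(design) {
  if (is.data.frame(design)) {
    if (!all(c("project", "parent", "n_subclones") %in% names(design)))
      stop("malformed replicate design: need project, parent, n_subclones")
    if (is.null(design$tech_reps)) design$tech_reps <- 1L
  } else if ((is.list(design) || is.numeric(design)) && !is.null(names(design))) {
    pp <- strsplit(names(design), "/", fixed = TRUE)
    if (any(lengths(pp) != 2L))
      stop("malformed replicate design: names must be 'Project/Parent'")
    design <- data.frame(project = vapply(pp, `[`, "", 1L),
                         parent = vapply(pp, `[`, "", 2L),
                         n_subclones = as.integer(unlist(design)),
                         tech_reps = 1L, stringsAsFactors = FALSE)
  } else stop("malformed replicate design")
  if (any(design$n_subclones < 1L) || any(design$tech_reps < 1L))
    stop("malformed replicate design: counts must be >= 1")
  design
}

.make_barcodes <- function(n, length = 8L, min_dist = 3L) {
  bcs <- character(0)
  while (length(bcs) < n) {
    b <- random_dna(length)
    ok <- TRUE
    for (x in bcs) if (cpp_hamming(b, x) < min_dist) { ok <- FALSE; break }
    if (ok) bcs <- c(bcs, b)
  }
  bcs
}

#' Simulate a whole sequencing run
#'
#' Generates clones for every parent cell line in the replicate design,
#' lays wells out over plates, optionally spikes a run-wide aberrant light
#' chain into a fraction of samples, and simulates every plate. Sample IDs
#' follow `Project/Parent.subclone`; technical replicates are additional
#' wells carrying the same sample ID.
#'
#' @param design replicate design: either a data.frame with columns
#'   `project`, `parent`, `n_subclones` (optionally `tech_reps`), or a named
#'   vector like `c("A/1" = 3)` mapping parent lines to subclone counts.
#' @param n_plates number of plates to spread wells over.
#' @param aberrant_chain a `clone_spec` providing the aberrant light chain,
#'   `TRUE` to generate one, or `NULL` for none.
#' @param aberrant_prevalence fraction of samples receiving the aberrant
#'   light chain (ceiling applied to the sample count).
#' @param aberrant_fraction within-chain read fraction of the aberrant
#'   light chain in spiked wells.
#' @param chain_classes chain classes each clone emits.
#' @param error_rate,reads_per_well,read_len per-plate simulation settings.
#' @param seed run seed; all per-plate and per-clone seeds derive from it.
#' @param outdir optional directory to write all plate files plus the truth
#'   table and clone region table.
#' @return List with `plates` (per-plate simulation outputs), `truth`,
#'   `clones`, `clone_regions`, `design`, `primer_set`, `tso`,
#'   `germline_pool` and `samples`.
#' @export
generate_run <- function(design, n_plates = 1L, aberrant_chain = NULL,
                         aberrant_prevalence = 0.5, aberrant_fraction = 0.3,
                         chain_classes = c("VL", "VH"), error_rate = 0.002,
                         reads_per_well = 200L, read_len = 300L, seed = 1L,
                         outdir = NULL) {
  design <- .normalize_design(design)
  if (aberrant_prevalence < 0 || aberrant_prevalence > 1)
    stop("aberrant_prevalence must be in [0, 1]")

  light_class <- intersect(chain_classes, LIGHT_TYPE_CHAINS)[1]
  run <- with_seed(seed, {
    clone_seeds <- sample.int(.Machine$integer.max - 1L, nrow(design) + 1L)
    clone_seeds
  })
  clones <- lapply(seq_len(nrow(design)), function(i)
    generate_clone(clone_seeds[i], chain_classes))
  names(clones) <- vapply(clones, `[[`, "", "clone_id")
  design$clone_id <- names(clones)

  ab_clone <- NULL
  if (isTRUE(aberrant_chain)) {
    ab_clone <- generate_clone(clone_seeds[nrow(design) + 1L], light_class)
    ab_clone$clone_id <- paste0(ab_clone$clone_id, "ab")
  } else if (inherits(aberrant_chain, "clone_spec")) {
    ab_clone <- aberrant_chain
    if (!light_class %in% names(ab_clone$chains))
      stop("aberrant_chain must carry a ", light_class, " chain")
  } else if (!is.null(aberrant_chain)) stop("invalid aberrant_chain")

  # One row per well; TRs are extra wells with the same sample ID.
  samples <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    data.frame(project = d$project, parent = d$parent,
               subclone = as.character(seq_len(d$n_subclones)),
               sample_id = sprintf("%s/%s.%d", d$project, d$parent,
                                   seq_len(d$n_subclones)),
               clone_id = d$clone_id, stringsAsFactors = FALSE)
  }))
  spiked <- character(0)
  if (!is.null(ab_clone)) {
    k <- as.integer(ceiling(aberrant_prevalence * nrow(samples)))
    # spread across parents: order by subclone index, then parent
    o <- order(as.integer(samples$subclone), samples$parent)
    spiked <- samples$sample_id[o][seq_len(k)]
  }
  wells_all <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    tr <- design$tech_reps[match(samples$parent[i], design$parent)]
    data.frame(sample_id = samples$sample_id[i], clone_id = samples$clone_id[i],
               rep = seq_len(tr), stringsAsFactors = FALSE)
  }))

  n_wells <- nrow(wells_all)
  per_plate <- as.integer(ceiling(n_wells / n_plates))
  if (per_plate > 96L) stop("more than 96 wells per plate; increase n_plates")
  well_ids <- paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, 8L))
  primer_set <- DEFAULT_PRIMERS[chain_classes]

  plate_seeds <- with_seed(seed + 1L, sample.int(.Machine$integer.max - 1L, n_plates))
  plates <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    rows <- wells_all[((p - 1L) * per_plate + 1L):min(p * per_plate, n_wells), ,
                      drop = FALSE]
    if (nrow(rows) == 0L) next
    bcs <- with_seed(plate_seeds[p], .make_barcodes(nrow(rows)))
    wells <- data.frame(well_id = well_ids[seq_len(nrow(rows))],
                        sample_id = rows$sample_id, barcode = bcs,
                        stringsAsFactors = FALSE)
    wc <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      sp <- rows$sample_id[i] %in% spiked
      frac_true_l <- if (sp) 1 - aberrant_fraction else 1
      out <- do.call(rbind, lapply(chain_classes, function(ch)
        data.frame(well_id = wells$well_id[i], clone_id = rows$clone_id[i],
                   chain = ch,
                   fraction = if (ch == light_class) frac_true_l else 1,
                   stringsAsFactors = FALSE)))
      if (sp)
        out <- rbind(out, data.frame(well_id = wells$well_id[i],
                                     clone_id = ab_clone$clone_id,
                                     chain = light_class,
                                     fraction = aberrant_fraction,
                                     stringsAsFactors = FALSE))
      out
    }))
    all_clones <- c(clones, if (!is.null(ab_clone)) setNames(list(ab_clone), ab_clone$clone_id))
    spec <- plate_spec(sprintf("plate%02d", p), wells, wc,
                       primer_set = primer_set, tso = DEFAULT_TSO,
                       error_rate = error_rate, reads_per_well = reads_per_well,
                       read_len = read_len, seed = plate_seeds[p])
    plates[[p]] <- generate_plate(spec, all_clones, outdir = outdir)
  }

  truth <- do.call(rbind, lapply(plates, function(p)
    cbind(plate_id = p$plate_id, p$truth, stringsAsFactors = FALSE)))
  clone_regions <- clone_region_table(c(clones, if (!is.null(ab_clone))
    setNames(list(ab_clone), ab_clone$clone_id)))
  germline_pool <- clone_regions
  germline_pool$fr_aa <- paste0(germline_pool$FR1, germline_pool$FR2,
                                germline_pool$FR3, germline_pool$FR4)

  out <- list(plates = plates, truth = truth, clones = clones,
              aberrant_clone = ab_clone, spiked_samples = spiked,
              clone_regions = clone_regions, design = design,
              samples = samples, primer_set = primer_set, tso = DEFAULT_TSO,
              germline_pool = germline_pool, seed = seed)
  if (!is.null(outdir)) {
    write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(clone_regions, file.path(outdir, "clone_regions.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write_primer_fasta(primer_set, file.path(outdir, "primers.fasta"))
    cfg <- list(
      plates = lapply(plates[!vapply(plates, is.null, logical(1))],
                      function(p) list(plate_id = p$plate_id,
                                       r1 = basename(p$files$r1),
                                       r2 = basename(p$files$r2),
                                       sample_sheet = basename(p$files$sample_sheet),
                                       barcodes = basename(p$files$barcodes))),
      primers = "primers.fasta", tso = DEFAULT_TSO,
      annotator = list(backend = "table", regions = "clone_regions.tsv"),
      seed = seed, outdir = file.path(outdir, "results"))
    yaml::write_yaml(cfg, file.path(outdir, "run.yaml"))
  }
  out
}

#' Region table for a set of clones
#'
#' One row per clone chain with the seven amino-acid region segments, the
#' variable-domain nucleotide offsets and the reading frame — the input the
#' table-driven annotator consumes.
#'
#' @param clones list of `clone_spec` objects.
#' @return data.frame with columns `clone_id`, `chain`, FR/CDR segments,
#'   `v_start`, `frame`, `nt`.
#' @export
clone_region_table <- function(clones) {
  do.call(rbind, unlist(lapply(clones, function(cl) {
    lapply(cl$chains, function(ch) {
      df <- as.data.frame(as.list(ch$regions), stringsAsFactors = FALSE)
      cbind(data.frame(clone_id = cl$clone_id, chain = ch$chain_class,
                       stringsAsFactors = FALSE),
            df,
            data.frame(v_start = ch$v_start, frame = ch$frame, nt = ch$nt,
                       stringsAsFactors = FALSE))
    })
  }), recursive = FALSE))
}
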