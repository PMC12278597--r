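# Run configuration: YAML in, validated RunConfig out, with defaults
# injected and validation errors aggregated into a single report.

.default_thresholds <- function() {
  list(min_overlap = 20L, max_mismatch_rate = 0.1, barcode_mismatches = 0L,
       primer_mismatches = 2L, tso_mismatches = 2L, q_min = 10L,
       min_len = 385L, max_hamming = 2L, abundance_ratio = 0.1,
       min_support = 0.10)
}

#' Load and validate a run configuration
#'
#' Parses a YAML run configuration, injects defaults for every omitted
#' threshold and scoring parameter, and validates it. All validation
#' failures are collected and reported together.
#'
#' @param path YAML file with fields `plates` (list of `plate_id`, `r1`,
#'   `r2`, `sample_sheet`, `barcodes`), `primers` (FASTA path), `tso`
#'   (sequence), optional `thresholds`, `scoring`, `annotator`
#'   (`backend`, `regions` path), `seed`, `outdir`.
#' @return A `run_config` list with components `plates`, `primers`, `tso`,
#'   `thresholds`, `scoring` ([scoring_params()]), `annotator`, `seed`,
#'   `outdir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  if (is.null(cfg$plates) || !length(cfg$plates)) note("no plates defined")
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else
    file.path(base, p)
  for (i in seq_along(cfg$plates)) {
    pl <- cfg$plates[[i]]
    for (f in c("r1", "r2", "sample_sheet", "barcodes")) {
      if (is.null(pl[[f]])) { note(sprintf("plate %d: missing '%s'", i, f)); next }
      cfg$plates[[i]][[f]] <- resolve(pl[[f]])
      if (!file.exists(cfg$plates[[i]][[f]]))
        note(sprintf("plate %d: file not found: %s", i, pl[[f]]))
    }
    if (is.null(pl$plate_id)) cfg$plates[[i]]$plate_id <- sprintf("plate%02d", i)
  }
  if (is.null(cfg$primers)) note("missing 'primers' (FASTA path)") else {
    cfg$primers <- resolve(cfg$primers)
    if (!file.exists(cfg$primers)) note(paste("primer FASTA not found:", cfg$primers))
  }
  if (is.null(cfg$tso) || !grepl("^[ACGT]+$", cfg$tso %||% ""))
    note("missing or invalid 'tso' sequence")

  thr <- utils::modifyList(.default_thresholds(), cfg$thresholds %||% list())
  if (thr$min_support < 0 || thr$min_support > 1)
    note("min_support must be in [0, 1]")
  if (thr$min_len < 1) note("min_len must be >= 1")
  if (thr$q_min < 0) note("q_min must be >= 0")
  if (thr$max_mismatch_rate < 0 || thr$max_mismatch_rate > 1)
    note("max_mismatch_rate must be in [0, 1]")

  sc <- cfg$scoring %||% list()
  scoring <- tryCatch(
    scoring_params(mu = sc$mu %||% 2, lam = sc$lam %||% 3, nu = sc$nu %||% 1,
                   high_conf_threshold = sc$high_conf_threshold %||% 4,
                   aberrant_prevalence = sc$aberrant_prevalence %||% 0.5,
                   literal_max = sc$literal_max %||% FALSE),
    error = function(e) { note(conditionMessage(e)); scoring_params() })

  ann <- cfg$annotator %||% list(backend = "table")
  if (!ann$backend %in% c("table", "motif"))
    note(paste("unknown annotator backend:", ann$backend))
  if (identical(ann$backend, "table")) {
    if (is.null(ann$regions)) note("table annotator requires 'regions' path")
    else {
      ann$regions <- resolve(ann$regions)
      if (!file.exists(ann$regions))
        note(paste("region table not found:", ann$regions))
    }
  }

  if (length(errs))
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))

  structure(list(plates = cfg$plates, primers = cfg$primers, tso = cfg$tso,
                 thresholds = thr, scoring = scoring, annotator = ann,
                 seed = as.integer(cfg$seed %||% 1L),
                 outdir = cfg$outdir %||% "."),
            class = "run_config")
}
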