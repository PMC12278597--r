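# High-confidence vs scrambled pairing dataset construction and a
# gradient-boosted classifier harness with grouped, leakage-free
# cross-validation.

#' Scramble heavy-chain assignments
#'
#' Builds the negative class: a seeded derangement of heavy chains over the
#' light-chain list, so no scrambled pair reunites an original couple. The
#' derangement is composed of disjoint transpositions over a seeded
#' shuffle (one 3-cycle absorbs an odd leftover), which keeps
#' chain-sharing components small enough for grouped cross-validation.
#'
#' @param pairs data.frame of original pairs (any columns; heavy-side
#'   columns are permuted). Needs at least 2 rows — no derangement exists
#'   for a single pair.
#' @param seed integer seed; the derangement is deterministic per seed.
#' @param heavy_cols columns belonging to the heavy chain (default: those
#'   whose name starts with `"heavy"` or `"vh"`).
#' @return `pairs` with the heavy-side columns deranged and an integer
#'   attribute `"derangement"` giving the permutation.
#' @export
scramble_pairs <- function(pairs, seed,
                           heavy_cols = grep("^(heavy|vh)", names(pairs),
                                             value = TRUE)) {
  n <- nrow(pairs)
  if (n < 2L) stop("need at least 2 pairs to scramble (no derangement exists)")
  if (!length(heavy_cols)) stop("no heavy-side columns identified")
  perm <- with_seed(seed, {
    o <- sample.int(n)
    p <- integer(n)
    k <- n - n %% 2L
    for (i in seq(1L, k - 1L, by = 2L)) {
      p[o[i]] <- o[i + 1L]
      p[o[i + 1L]] <- o[i]
    }
    if (n %% 2L == 1L) {       # 3-cycle over the last shuffled triple
      a <- o[n - 2L]; b <- o[n - 1L]; c <- o[n]
      p[a] <- b; p[b] <- c; p[c] <- a
    }
    p
  })
  out <- pairs
  out[heavy_cols] <- pairs[perm, heavy_cols, drop = FALSE]
  attr(out, "derangement") <- perm
  out
}

PAIR_FEATURE_NAMES <- c(
  "light_cdr3_len", "heavy_cdr3_len",
  paste0("light_", tolower(REGION_NAMES), "_len"),
  paste0("heavy_", tolower(REGION_NAMES), "_len"),
  "light_is_vl", "light_is_alpha", "light_is_gamma",
  "heavy_is_vh", "heavy_is_beta", "heavy_is_delta",
  "light_germ_ident", "heavy_germ_ident",
  "cdr3_len_diff", "total_len_diff"
)

#' Germline-similarity feature provider
#'
#' Returns a function scoring a chain's percent identity to its nearest
#' germline in a synthetic pool (e.g. the simulator's framework-region
#' concatenations), as a stand-in for a germline-assignment tool.
#'
#' @param pool character vector of germline amino-acid sequences.
#' @return `function(aa) -> identity in [0, 1]` (1 - normalised edit
#'   distance to the nearest pool member); the empty pool yields 0.5.
#' @export
germline_provider <- function(pool) {
  force(pool)
  function(aa) {
    if (!length(pool)) return(0.5)
    d <- utils::adist(aa, pool)[1, ]
    max(1 - d / pmax(nchar(aa), nchar(pool)))
  }
}

#' Feature vector for a candidate pair
#'
#' Fixed-length, order-stable numeric features: CDR3 lengths, all 14 region
#' lengths, chain-class indicators, germline-similarity stubs and length
#' differences.
#'
#' @param light,heavy chain summaries: lists (or one-row data.frames) with
#'   `chain_class` and named FR/CDR region segments (`regions` list or
#'   FR1..CDR3 fields).
#' @param germline optional [germline_provider()]; absent, the similarity
#'   stubs are 0.5.
#' @return Named numeric vector of length `length(PAIR_FEATURE_NAMES)`.
#' @export
featurize_pair <- function(light, heavy, germline = NULL) {
  g <- germline %||% function(aa) 0.5
  side <- function(x, prefix, classes) {
    regs <- if (!is.null(x$regions)) unlist(x$regions) else
      unlist(x[REGION_NAMES])
    if (is.null(x$chain_class) || any(is.na(regs)) ||
        length(regs) != length(REGION_NAMES))
      stop("missing annotation for ", prefix, " chain")
    names(regs) <- REGION_NAMES
    aa <- paste(regs, collapse = "")
    v <- c(setNames(nchar(regs), paste0(prefix, "_", tolower(REGION_NAMES), "_len")),
           setNames(as.numeric(x$chain_class == classes),
                    paste0(prefix, "_is_", tolower(sub("^V", "v", classes)))),
           setNames(g(aa), paste0(prefix, "_germ_ident")))
    attr(v, "cdr3") <- nchar(regs[["CDR3"]])
    attr(v, "total") <- nchar(aa)
    v
  }
  l <- side(light, "light", LIGHT_TYPE_CHAINS)
  h <- side(heavy, "heavy", HEAVY_TYPE_CHAINS)
  feats <- c(light_cdr3_len = unname(attr(l, "cdr3")),
             heavy_cdr3_len = unname(attr(h, "cdr3")),
             l[paste0("light_", tolower(REGION_NAMES), "_len")],
             h[paste0("heavy_", tolower(REGION_NAMES), "_len")],
             l["light_is_vl"], l["light_is_alpha"], l["light_is_gamma"],
             h["heavy_is_vh"], h["heavy_is_beta"], h["heavy_is_delta"],
             l["light_germ_ident"], h["heavy_germ_ident"],
             cdr3_len_diff = unname(attr(h, "cdr3") - attr(l, "cdr3")),
             total_len_diff = unname(attr(h, "total") - attr(l, "total")))
  stopifnot(identical(names(feats), PAIR_FEATURE_NAMES))
  feats
}

# Connected components of candidates linked by a shared chain sequence
# (union-find). Used for leakage-free grouped splitting.
.sequence_groups <- function(light_aa, heavy_aa) {
  n <- length(light_aa)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  link <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  for (key in list(light_aa, heavy_aa)) {
    firsts <- split(seq_len(n), key)
    for (idx in firsts) if (length(idx) > 1L)
      for (j in idx[-1]) link(idx[1], j)
  }
  vapply(seq_len(n), find, integer(1))
}

.fit_gbt <- function(X, y, nrounds, max_depth, eta) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1L),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = nrounds, verbose = 0)
}

.rank_auc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build labelled pairing candidates from a scored run
#'
#' Positives are the high-confidence pairs of [select_high_confidence_pairs()];
#' negatives are a seeded derangement of their heavy chains. Region
#' annotations are joined back from the scored table and the feature matrix
#' is computed.
#'
#' @param scored output of [score_run()].
#' @param params a [scoring_params()].
#' @param seed derangement seed.
#' @param germline optional [germline_provider()].
#' @return data.frame with `label` (1 high-confidence, 0 scrambled),
#'   `light_aa`, `heavy_aa` and one column per feature.
#' @export
build_pair_candidates <- function(scored, params = scoring_params(), seed = 1L,
                                  germline = NULL) {
  pos <- select_high_confidence_pairs(scored, params)
  if (nrow(pos) < 2L)
    stop("need at least 2 high-confidence pairs to build a training set")
  neg <- scramble_pairs(pos, seed = seed,
                        heavy_cols = c("heavy_aa", "heavy_nt", "heavy_score"))
  lookup <- scored[!duplicated(paste(scored$chain_class, scored$aa_vdomain)), ,
                   drop = FALSE]
  chain_of <- function(aa) {
    i <- match(aa, lookup$aa_vdomain)
    list(chain_class = lookup$chain_class[i],
         regions = as.list(lookup[i, REGION_NAMES]))
  }
  featurize_set <- function(df, label) {
    feats <- t(vapply(seq_len(nrow(df)), function(i)
      featurize_pair(chain_of(df$light_aa[i]), chain_of(df$heavy_aa[i]),
                     germline = germline),
      numeric(length(PAIR_FEATURE_NAMES))))
    cbind(data.frame(label = label, light_aa = df$light_aa,
                     heavy_aa = df$heavy_aa, stringsAsFactors = FALSE),
          as.data.frame(feats))
  }
  rbind(featurize_set(pos, 1L), featurize_set(neg, 0L))
}

#' Train and evaluate the pairing classifier
#'
#' Grouped, stratified k-fold cross-validation of a gradient-boosted tree
#' classifier over pair features. Grouping is by chain sequence: candidates
#' sharing a light or heavy amino-acid sequence always land in the same
#' fold, so no sequence leaks between training and held-out data. Metrics
#' are computed on the pooled held-out predictions; a final model is fitted
#' on all data.
#'
#' @param candidates data.frame from [build_pair_candidates()] (columns
#'   `label`, `light_aa`, `heavy_aa`, features).
#' @param folds number of folds (default 5).
#' @param seed seed controlling fold assignment and the booster.
#' @param nrounds,max_depth,eta fixed booster hyperparameters.
#' @return A `pair_cv` object: `metrics` (accuracy, precision, recall, f1,
#'   roc_auc), `folds`, `seed`, `predictions` (held-out), and `model`
#'   (final xgboost booster).
#' @export
train_eval <- function(candidates, folds = 5L, seed = 1L, nrounds = 60L,
                       max_depth = 3L, eta = 0.3) {
  y <- as.integer(candidates$label)
  if (length(unique(y)) < 2L) stop("single-class input: cannot train")
  X <- as.matrix(candidates[, PAIR_FEATURE_NAMES, drop = FALSE])
  grp <- .sequence_groups(candidates$light_aa, candidates$heavy_aa)

  # assign groups to folds: largest first, to the emptiest fold
  sizes <- sort(table(grp), decreasing = TRUE)
  fold_of_group <- integer(0)
  load <- numeric(folds)
  for (g in names(sizes)) {
    f <- which.min(load)
    fold_of_group[g] <- f
    load[f] <- load[f] + sizes[[g]]
  }
  fold <- fold_of_group[as.character(grp)]
  if (length(unique(fold)) < 2L)
    stop("grouped splitting degenerate: all candidates share sequences")

  prob <- rep(NA_real_, length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L)
      stop("a training fold is single-class; use fewer folds")
    set.seed(seed)
    booster <- .fit_gbt(X[tr, , drop = FALSE], y[tr], nrounds, max_depth, eta)
    prob[!tr] <- predict(booster, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
  }
  pred <- as.integer(prob > 0.5)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  metrics <- list(
    accuracy = mean(pred == y),
    precision = precision,
    recall = recall,
    f1 = if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0,
    roc_auc = .rank_auc(y, prob))

  set.seed(seed)
  final <- .fit_gbt(X, y, nrounds, max_depth, eta)
  structure(list(metrics = metrics, folds = as.integer(folds),
                 seed = as.integer(seed),
                 predictions = data.frame(label = y, prob = prob,
                                          fold = fold, group = grp),
                 model = final, feature_names = PAIR_FEATURE_NAMES),
            class = "pair_cv")
}

#' @export
print.pair_cv <- function(x, ...) {
  cat(sprintf("Grouped %d-fold CV of the pairing classifier (seed %d, n = %d)\n",
              x$folds, x$seed, nrow(x$predictions)))
  m <- x$metrics
  cat(sprintf("  accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f | ROC-AUC %.3f\n",
              m$accuracy, m$precision, m$recall, m$f1, m$roc_auc))
  invisible(x)
}

#' Save / load a pairing model with its feature schema
#'
#' @param cv a `pair_cv` object (or a list with `model` and
#'   `feature_names`).
#' @param path output path; the booster is stored as base64 inside a JSON
#'   wrapper carrying a schema version and the feature order.
#' @export
save_pair_model <- function(cv, path) {
  raw <- xgboost::xgb.save.raw(cv$model)
  obj <- list(schema_version = 1L, feature_names = cv$feature_names,
              model_b64 = jsonlite::base64_enc(raw))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_pair_model
#' @export
load_pair_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(obj$schema_version), 1L))
    stop("unknown pairing-model schema version: ", obj$schema_version)
  list(model = xgboost::xgb.load.raw(jsonlite::base64_dec(obj$model_b64)),
       feature_names = obj$feature_names)
}
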