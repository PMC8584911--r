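#' Run a multi-run CAE (mrCAE) system
#'
#' Trains `n_runs` independent concrete autoencoders on the same data, run
#' `i` seeded with `base_seed + i`, and returns the list of [CAERun-class]
#' results.  Because seeds are positional, the first `m` runs of an `R`-run
#' system are exactly an `m`-run system: nested systems (10-, 20-, ...-run)
#' can be built as prefixes of one pool without retraining.
#'
#' When `out_dir` is given each finished run is persisted immediately as
#' `run_<seed>.json`; an existing file for a seed is re-read instead of
#' retrained, so interrupted jobs resume where they stopped.
#'
#' @param x a normalized [ExprMatrix-class].
#' @param cfg a [CAEConfig-class]; its `seed` slot is overridden per run.
#' @param n_runs number of independent runs (>= 1).
#' @param base_seed integer; run `i` uses seed `base_seed + i`.
#' @param labels optional named factor passed to [trainCAE()].
#' @param out_dir optional directory for incremental JSON persistence.
#' @param verbose print one line per finished run.
#' @return list of [CAERun-class], in run order.
#' @seealso [frequencyTable()], [topStableFeatures()]
#' @export
runMrCAE <- function(x, cfg, n_runs, base_seed = 0L, labels = NULL,
                     out_dir = NULL, verbose = FALSE) {
  stopifnot(n_runs >= 1L)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    seed <- as.integer(base_seed) + i
    path <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("run_%d.json", seed))
    if (!is.null(path) && file.exists(path)) {
      runs[[i]] <- readRunJSON(path)
    } else {
      cfg_i <- cfg; cfg_i@seed <- seed
      runs[[i]] <- tryCatch(trainCAE(x, cfg_i, labels = labels),
        error = function(e)
          stop("mrCAE run ", i, " (seed ", seed, ") failed: ",
               conditionMessage(e)))
      if (!is.null(path)) writeRunJSON(runs[[i]], path)
    }
    if (verbose)
      message(sprintf("run %d/%d (seed %d): %d unique features, val MSE %.4g",
                      i, n_runs, seed, length(selectedFeatures(runs[[i]])),
                      valMSE(runs[[i]])))
  }
  runs
}

#' Cross-run feature frequency table
#'
#' Tallies, over a list of runs, how many runs selected each feature.  A
#' feature picked by several selector nodes within one run still counts once
#' for that run (frequencies count runs, not nodes).  The result is
#' invariant under permutation of the run list.
#'
#' @param runs non-empty list of [CAERun-class] objects, or of character
#'   vectors of selected feature IDs.
#' @return A [FrequencyTable-class].
#' @examples
#' ft <- frequencyTable(list(c("f1", "f2"), c("f2", "f3")))
#' featureFrequencies(ft)   # f1:1 f2:2 f3:1
#' @export
frequencyTable <- function(runs) {
  if (!length(runs)) stop("no runs to aggregate")
  sets <- lapply(runs, function(r)
    if (is(r, "CAERun")) selectedFeatures(r) else unique(as.character(r)))
  tab <- table(unlist(sets, use.names = FALSE))
  counts <- stats::setNames(as.integer(tab), names(tab))
  new("FrequencyTable", counts = counts, totalRuns = length(runs))
}

#' Top-N stable features
#'
#' Ranks the features of a [FrequencyTable-class] by descending cross-run
#' frequency and keeps the first `n`.  Ties are broken by feature ID
#' ascending, a documented deterministic rule.  `min_frequency = 2`
#' restricts the ranking to "frequent" features (selected in more than one
#' run) before truncation.
#'
#' @param x a [FrequencyTable-class].
#' @param n number of features requested (>= 1); if larger than the table,
#'   the full ranking is returned.
#' @param min_frequency keep only features with at least this frequency
#'   (default 1 = no filter).
#' @return A [StableFeatureSet-class].
#' @export
topStableFeatures <- function(x, n, min_frequency = 1L) {
  stopifnot(is(x, "FrequencyTable"), n >= 1L)
  cnt <- x@counts[x@counts >= min_frequency]
  ord <- order(-cnt, names(cnt))
  keep <- ord[seq_len(min(as.integer(n), length(ord)))]
  new("StableFeatureSet",
      ranked = data.frame(feature_id = names(cnt)[keep],
                          frequency = as.integer(cnt[keep]),
                          stringsAsFactors = FALSE),
      nRequested = as.integer(n),
      tieRule = "frequency desc, feature_id asc")
}

#' Stability report across mrCAE systems
#'
#' Summarizes one or more mrCAE systems (frequency tables built from
#' different numbers of runs): per system the number of distinct features
#' ever selected and the min/max frequency, and per (system, Top-N) the
#' frequency range within the Top-N ranking -- the machine-readable
#' analogues of the summary tables used to pick an operating number of runs.
#'
#' @param tables list of [FrequencyTable-class], one per system.
#' @param top_sizes integer vector of Top-N sizes (default
#'   `c(10, 20, 40, 60, 80, 100)`).
#' @return list with data.frames `summary` (system, n_runs, total_features,
#'   min_frequency, max_frequency) and `ranges` (system, n_runs, top_n,
#'   freq_min, freq_max).
#' @export
stabilityReport <- function(tables, top_sizes = c(10L, 20L, 40L, 60L, 80L, 100L)) {
  stopifnot(length(tables) >= 1L)
  if (is(tables, "FrequencyTable")) tables <- list(tables)
  nm <- names(tables)
  if (is.null(nm)) nm <- paste0(vapply(tables, totalRuns, 1L), "-run")
  summ <- do.call(rbind, lapply(seq_along(tables), function(i) {
    ft <- tables[[i]]
    data.frame(system = nm[i], n_runs = totalRuns(ft),
               total_features = length(ft@counts),
               min_frequency = min(ft@counts),
               max_frequency = max(ft@counts),
               stringsAsFactors = FALSE)
  }))
  ranges <- do.call(rbind, lapply(seq_along(tables), function(i) {
    ft <- tables[[i]]
    do.call(rbind, lapply(top_sizes, function(N) {
      r <- topStableFeatures(ft, N)@ranked$frequency
      data.frame(system = nm[i], n_runs = totalRuns(ft), top_n = N,
                 freq_min = min(r), freq_max = max(r),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(summary = summ, ranges = ranges)
}

#' Union of stable feature sets
#'
#' Unites the member features of several [StableFeatureSet-class] objects
#' (or plain character vectors) -- e.g. the Top-100 sets of systems with
#' different run counts -- into one consensus feature list.  When the sets
#' are nested the union equals the largest set.
#'
#' @param stable_sets non-empty list of [StableFeatureSet-class] or
#'   character vectors.
#' @return character vector of distinct feature IDs (sorted).
#' @export
consensusUnion <- function(stable_sets) {
  if (!length(stable_sets)) stop("no sets to unite")
  ids <- lapply(stable_sets, function(s)
    if (is(s, "StableFeatureSet")) s@ranked$feature_id else as.character(s))
  sort(unique(unlist(ids, use.names = FALSE)))
}

#' Persist / restore a CAE run as JSON
#'
#' `writeRunJSON` serializes the selection outcome of a run (seed, config,
#' per-node picks, unique features, characteristic trace, held-out MSE) to a
#' JSON file; decoder weights are not serialized.  `readRunJSON` restores a
#' lightweight [CAERun-class] sufficient for aggregation and reporting (its
#' `decoder` and `selectorLogits` slots are empty).
#'
#' @param run a [CAERun-class].
#' @param path JSON file path.
#' @return `writeRunJSON` returns `invisible(path)`; `readRunJSON` a
#'   [CAERun-class].
#' @export
writeRunJSON <- function(run, path) {
  stopifnot(is(run, "CAERun"))
  cfg <- run@config
  obj <- list(
    seed = run@seed,
    config = list(k = cfg@k, hidden_sizes = cfg@hiddenSizes,
                  leaky_relu_slope = cfg@leakyReluSlope,
                  dropout_rate = cfg@dropoutRate, epochs = cfg@epochs,
                  learning_rate = cfg@learningRate, t_start = cfg@tStart,
                  t_end = cfg@tEnd, batch_size = cfg@batchSize),
    per_node_pick = run@nodePicks,
    selected_unique = run@selectedUnique,
    val_mse = run@valMSE,
    trace = as.list(run@trace))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRunJSON
#' @export
readRunJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- caeConfig(k = obj$config$k, hiddenSizes = obj$config$hidden_sizes,
                   leakyReluSlope = obj$config$leaky_relu_slope,
                   dropoutRate = obj$config$dropout_rate,
                   epochs = obj$config$epochs,
                   learningRate = obj$config$learning_rate,
                   tStart = obj$config$t_start, tEnd = obj$config$t_end,
                   batchSize = obj$config$batch_size, seed = obj$seed)
  new("CAERun",
      selectedUnique = as.character(obj$selected_unique),
      nodePicks = as.character(obj$per_node_pick),
      trace = as.data.frame(obj$trace), valMSE = as.numeric(obj$val_mse),
      config = cfg, seed = as.integer(obj$seed),
      selectorLogits = matrix(numeric(), 0, 0), decoder = list(),
      featureIDs = character())
}
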