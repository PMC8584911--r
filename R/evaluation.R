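#' Score a feature subset by stratified k-fold linear-SVM classification
#'
#' Restricts the expression matrix to `features`, runs stratified `n_folds`
#' cross-validation with a linear-kernel SVM (libsvm via \pkg{e1071}, cost
#' fixed at 1, inputs used as-is), and reports accuracy and macro-averaged
#' precision, recall and F1 per fold plus their means.  Fold assignment is
#' stratified per class and deterministic for a fixed `seed`, so different
#' feature sets scored with the same seed are compared on identical folds.
#'
#' Macro averaging (unweighted mean over classes) is used because the
#' intended setting -- a dozen cancer types of very different cohort sizes --
#' makes micro averages nearly duplicate accuracy.  A class never predicted
#' contributes precision 0 (the usual zero-division convention).
#'
#' @param x an [ExprMatrix-class].
#' @param labels named factor of class labels (names = sample IDs), at least
#'   2 classes, every class with at least `n_folds` samples.
#' @param features non-empty character vector of feature IDs, all present in
#'   `x`.
#' @param n_folds number of folds (default 5).
#' @param seed integer controlling fold assignment.
#' @param cost SVM regularization constant (default 1, not tuned).
#' @return list of class `"svmMetrics"`: aggregate `accuracy`, `precision`,
#'   `recall`, `f1` (means over folds), `per_fold` data.frame, `n_folds`,
#'   `cost`.
#' @seealso [compareFeatureSets()]
#' @export
scoreFeatureSet <- function(x, labels, features, n_folds = 5L, seed = 1L,
                            cost = 1) {
  stopifnot(is(x, "ExprMatrix"))
  features <- unique(as.character(features))
  if (!length(features)) stop("empty feature set")
  miss <- setdiff(features, featureIDs(x))
  if (length(miss))
    stop("feature(s) not in matrix: ", paste(head(miss, 3L), collapse = ", "))
  lab <- alignLabels(labels, sampleIDs(x))
  folds <- stratifiedFolds(lab, n_folds, seed)
  evalFolds(exprValues(x)[, features, drop = FALSE], lab, folds, cost)
}

# Stratified fold assignment: within each class, shuffled balanced fold ids.
stratifiedFolds <- function(lab, n_folds, seed) {
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 2L)
  if (nlevels(lab) < 2L) stop("need at least 2 classes, got ", nlevels(lab))
  sizes <- table(lab)
  small <- names(sizes)[sizes < n_folds]
  if (length(small))
    stop("class(es) smaller than n_folds: ", paste(small, collapse = ", "))
  folds <- integer(length(lab))
  withSeed(seed, {
    for (cl in levels(lab)) {
      idx <- which(lab == cl)
      folds[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
    }
  })
  folds
}

evalFolds <- function(v, lab, folds, cost = 1) {
  n_folds <- max(folds)
  per <- lapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    fit <- e1071::svm(x = v[tr, , drop = FALSE], y = lab[tr],
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- predict(fit, v[!tr, , drop = FALSE])
    truth <- lab[!tr]
    cm <- table(factor(truth, levels(lab)), factor(pred, levels(lab)))
    tp <- diag(cm)
    prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
    rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    data.frame(fold = f, accuracy = mean(pred == truth),
               precision = mean(prec), recall = mean(rec), f1 = mean(f1))
  })
  per <- do.call(rbind, per)
  out <- list(accuracy = mean(per$accuracy), precision = mean(per$precision),
              recall = mean(per$recall), f1 = mean(per$f1),
              per_fold = per, n_folds = n_folds, cost = cost)
  class(out) <- "svmMetrics"
  out
}

#' @export
print.svmMetrics <- function(x, ...) {
  cat(sprintf(
    "%d-fold linear SVM (C = %g): accuracy %.3f, macro precision %.3f, recall %.3f, F1 %.3f\n",
    x$n_folds, x$cost, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Compare several feature sets on common folds
#'
#' Scores each named feature set with [scoreFeatureSet()] using the same
#' seed, hence identical fold assignments, so the rows are a paired
#' comparison (e.g. a stable mrCAE set against single-run selections or
#' externally produced baseline lists).
#'
#' @inheritParams scoreFeatureSet
#' @param named_sets named list of feature-ID vectors.
#' @return data.frame with one row per set: `set`, `n_features`, `accuracy`,
#'   `precision`, `recall`, `f1`; per-fold tables in
#'   `attr(, "per_fold")`.
#' @export
compareFeatureSets <- function(x, labels, named_sets, n_folds = 5L,
                               seed = 1L, cost = 1) {
  stopifnot(is.list(named_sets), length(named_sets) >= 1L)
  if (is.null(names(named_sets)) || any(!nzchar(names(named_sets))))
    stop("named_sets must be a fully named list")
  res <- lapply(names(named_sets), function(nm) {
    m <- tryCatch(
      scoreFeatureSet(x, labels, named_sets[[nm]], n_folds, seed, cost),
      error = function(e) stop("set '", nm, "': ", conditionMessage(e)))
    m
  })
  out <- data.frame(
    set = names(named_sets),
    n_features = vapply(named_sets, function(s) length(unique(s)), 1L),
    accuracy = vapply(res, `[[`, 1, "accuracy"),
    precision = vapply(res, `[[`, 1, "precision"),
    recall = vapply(res, `[[`, 1, "recall"),
    f1 = vapply(res, `[[`, 1, "f1"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "per_fold") <- stats::setNames(lapply(res, `[[`, "per_fold"),
                                           names(named_sets))
  out
}

#' Overlap summary of feature sets
#'
#' Exact intersection cardinalities for every combination of 2 to
#' `length(sets)` sets (the numbers behind a Venn diagram), plus each set's
#' size and the size of the common core.
#'
#' @param sets named list of 2--6 feature-ID vectors.
#' @return list with `sizes` (named integer), `intersections` (data.frame
#'   `combination`, `degree`, `size`) and `common` (the intersection of all
#'   sets).
#' @export
overlapSummary <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, length(sets) <= 6L)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  nm <- names(sets)
  combos <- unlist(lapply(2:length(sets), function(d)
    utils::combn(nm, d, simplify = FALSE)), recursive = FALSE)
  inter <- data.frame(
    combination = vapply(combos, paste, "", collapse = " & "),
    degree = vapply(combos, length, 1L),
    size = vapply(combos, function(cc)
      length(Reduce(intersect, sets[cc])), 1L),
    stringsAsFactors = FALSE)
  list(sizes = vapply(sets, length, 1L),
       intersections = inter,
       common = sort(Reduce(intersect, sets)))
}

#' Random-search tuning of epochs and learning rate
#'
#' Draws `n_trials` (epochs, learning rate) pairs uniformly from the given
#' grids, trains one concrete autoencoder per draw, scores its selected
#' features with [scoreFeatureSet()] on folds shared across trials, and
#' returns the accuracy-maximizing configuration together with the full
#' trial log.  Failed trials are logged with `NA` metrics and do not abort
#' the search.  Deterministic for fixed `seed` (trial `i` trains with seed
#' `seed + i`).
#'
#' @param x a normalized [ExprMatrix-class].
#' @param labels named factor of class labels.
#' @param cfg template [CAEConfig-class]; epochs/learningRate/seed are
#'   overridden per trial.
#' @param epoch_grid,lr_grid non-empty candidate values.
#' @param n_trials number of random draws (>= 1).
#' @param seed integer driving the draws, the per-trial training seeds and
#'   the scoring folds.
#' @param n_folds folds for scoring (default 5).
#' @return list with `best` (a [CAEConfig-class]) and `log` (data.frame:
#'   trial, epochs, learning_rate, accuracy, f1, val_mse).
#' @export
randomSearchTune <- function(x, labels, cfg, epoch_grid, lr_grid,
                             n_trials = 8L, seed = 1L, n_folds = 5L) {
  stopifnot(length(epoch_grid) >= 1L, length(lr_grid) >= 1L, n_trials >= 1L)
  withSeed(seed, {
    eps <- epoch_grid[sample.int(length(epoch_grid), n_trials, replace = TRUE)]
    lrs <- lr_grid[sample.int(length(lr_grid), n_trials, replace = TRUE)]
  })
  log <- data.frame(trial = seq_len(n_trials), epochs = as.integer(eps),
                    learning_rate = lrs, accuracy = NA_real_, f1 = NA_real_,
                    val_mse = NA_real_)
  best <- NULL; best_acc <- -Inf
  for (i in seq_len(n_trials)) {
    cfg_i <- cfg
    cfg_i@epochs <- as.integer(eps[i])
    cfg_i@learningRate <- as.numeric(lrs[i])
    cfg_i@seed <- as.integer(seed + i)
    res <- tryCatch({
      run <- trainCAE(x, cfg_i, labels = labels)
      met <- scoreFeatureSet(x, labels, selectedFeatures(run), n_folds, seed)
      list(acc = met$accuracy, f1 = met$f1, mse = valMSE(run))
    }, error = function(e) {
      warning("trial ", i, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      log$accuracy[i] <- res$acc; log$f1[i] <- res$f1; log$val_mse[i] <- res$mse
      if (res$acc > best_acc) { best_acc <- res$acc; best <- cfg_i }
    }
  }
  if (is.null(best)) stop("every tuning trial failed")
  list(best = best, log = log)
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  eval.parent(substitute(expr))
}
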