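#' Read an expression table from TSV
#'
#' Reads a tab-separated expression table with a header row and IDs in the
#' first column.  The in-memory convention is always samples in rows and
#' features in columns; files stored the other way round are handled by
#' `transpose = TRUE`.
#'
#' @param path path to a TSV file (UTF-8, header row, first column = row IDs).
#' @param transpose logical; set `TRUE` when the file stores features in rows
#'   and samples in columns.
#' @param normalized logical; mark the result as already min-max normalized
#'   (validated against the values).
#' @return An [ExprMatrix-class].
#' @details Any cell that does not parse as a finite number (including `NA`)
#'   is an error reporting the offending row and column, and duplicate sample
#'   or feature IDs are rejected -- silent coercion would corrupt downstream
#'   frequency tables keyed by ID.
#' @seealso [writeExpression()], [minMaxNormalize()]
#' @export
readExpression <- function(path, transpose = FALSE, normalized = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("expression table needs an ID column plus data")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1L]))
    stop("duplicate column IDs in ", path)
  body <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim(body)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric cell '%s' at row '%s', column '%s' in %s",
      body[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
      colnames(df)[-1L][bad[1, 2]], path))
  }
  dimnames(vals) <- list(ids, colnames(df)[-1L])
  if (transpose) vals <- t(vals)
  ExprMatrix(vals, normalized = normalized)
}

#' Write an expression table to TSV
#'
#' Inverse of [readExpression()]: writes samples in rows (or features in rows
#' with `transpose = TRUE`) with an `id` header for the ID column.  Values are
#' written with full precision, so a write/read round trip reproduces the
#' matrix exactly for decimal-representable values.
#'
#' @param x an [ExprMatrix-class].
#' @param path output file path.
#' @param transpose logical; write features in rows instead.
#' @return `invisible(path)`.
#' @export
writeExpression <- function(x, path, transpose = FALSE) {
  stopifnot(is(x, "ExprMatrix"))
  v <- exprValues(x)
  if (transpose) v <- t(v)
  # %.17g preserves every double exactly across a write/read round trip
  body <- array(sprintf("%.17g", v), dim(v), dimnames = dimnames(v))
  df <- data.frame(id = rownames(v), body, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-label table
#'
#' Two-column TSV (`sample_id`, `label`, header required, extra columns
#' ignored) mapping sample to class (e.g. cancer type).
#'
#' @param path path to the TSV.
#' @return named factor of labels, names = sample IDs.
#' @export
readLabels <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("label table needs sample_id and label columns")
  if (anyDuplicated(df[[1L]])) stop("duplicate sample IDs in ", path)
  stats::setNames(factor(df[[2L]]), df[[1L]])
}

#' Read a clinical (survival) table
#'
#' TSV with columns `sample_id`, `time`, `event` (header required).  Survival
#' times must be positive; the time unit is treated as opaque and must simply
#' be consistent within a table.  `event` is 1 for death/event, 0 for
#' censoring.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `sample_id` (character), `time` (numeric),
#'   `event` (integer 0/1).
#' @export
readClinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   quote = "")
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$sample_id),
                    time = as.numeric(df$time),
                    event = as.integer(df$event),
                    stringsAsFactors = FALSE)
  validateClinical(out)
  out
}

validateClinical <- function(clin) {
  if (anyDuplicated(clin$sample_id)) stop("duplicate sample IDs in clinical table")
  if (any(!is.finite(clin$time)) || any(clin$time <= 0))
    stop("survival times must be positive and finite")
  if (!all(clin$event %in% c(0L, 1L)))
    stop("event indicator must be 0 (censored) or 1 (event)")
  invisible(clin)
}

#' Per-feature min-max normalization
#'
#' Maps every feature column through `(x - min) / (max - min)` so each
#' feature spans \[0, 1\], the scaling used before autoencoder training.
#' Statistics are computed on the full matrix (the split into training and
#' validation happens afterwards, inside [trainCAE()]); see the package
#' vignette for the information-leakage implication of that ordering.
#' Constant (zero-variance) features are mapped to all zeros: they carry no
#' signal, and dropping them would silently change the feature space.
#'
#' @param x an [ExprMatrix-class], not yet normalized.
#' @return A normalized [ExprMatrix-class] of the same dimensions.
#' @examples
#' m <- matrix(c(0, 5, 10, 3, 3, 3), 3, 2,
#'             dimnames = list(paste0("s", 1:3), c("fA", "fB")))
#' exprValues(minMaxNormalize(ExprMatrix(m)))
#' @export
minMaxNormalize <- function(x) {
  stopifnot(is(x, "ExprMatrix"))
  if (isNormalized(x)) stop("matrix is already normalized")
  v <- exprValues(x)
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1           # avoid 0/0; constant columns become all-zero
  out <- sweep(sweep(v, 2L, lo, "-"), 2L, rng, "/")
  out[, const] <- 0
  ExprMatrix(out, normalized = TRUE)
}

#' Stratified train/test split
#'
#' Splits samples into train and test sets, preserving class proportions per
#' label to within one sample.  Without labels the split is simple random.
#' Deterministic for a fixed `seed`.
#'
#' @param x an [ExprMatrix-class] (or anything with [sampleIDs()]).
#' @param labels optional named factor (names = sample IDs) to stratify on;
#'   every class needs at least 2 samples.
#' @param test_fraction fraction of samples held out, strictly in (0, 1).
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @return list with integer index vectors `train` and `test`, a partition of
#'   `seq_along(sampleIDs(x))`.
#' @export
stratifiedSplit <- function(x, labels = NULL, test_fraction = 0.2,
                            seed = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  ids <- sampleIDs(x)
  n <- length(ids)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(labels)) {
    n_test <- max(1L, round(n * test_fraction))
    test <- sort(sample.int(n, n_test))
  } else {
    lab <- alignLabels(labels, ids)
    sizes <- table(lab)
    if (any(sizes < 2L))
      stop("class(es) with a single sample cannot be split: ",
           paste(names(sizes)[sizes < 2L], collapse = ", "))
    test <- integer()
    for (cl in levels(lab)) {
      idx <- which(lab == cl)
      n_test <- max(1L, round(length(idx) * test_fraction))
      n_test <- min(n_test, length(idx) - 1L)   # keep >= 1 train sample
      test <- c(test, sample(idx, n_test))
    }
    test <- sort(test)
  }
  list(train = setdiff(seq_len(n), test), test = test)
}

# Align a named label vector to a sample-ID vector; error on missing IDs.
alignLabels <- function(labels, ids) {
  if (is.null(names(labels)))
    stop("labels must be named by sample ID")
  miss <- setdiff(ids, names(labels))
  if (length(miss))
    stop("labels missing for ", length(miss), " sample(s), e.g. ", miss[1L])
  droplevels(factor(labels[ids]))
}
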