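#' @useDynLib mrcae, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is setClass setGeneric setMethod
#'   setValidity show slot
#' @importFrom stats median pchisq predict quantile rnorm runif rexp sd
#'   uniroot complete.cases
#' @importFrom utils read.delim write.table head
#' @import SummarizedExperiment
NULL

#' Expression matrix container
#'
#' `ExprMatrix` holds a samples-by-features expression table inside a
#' [SummarizedExperiment::SummarizedExperiment] (features in rows, samples in
#' columns, the Bioconductor convention) together with a flag recording
#' whether per-feature min-max normalization has been applied.  All
#' user-facing functions in this package speak the samples-by-features
#' orientation through [exprValues()]; the transposition is internal.
#'
#' Validity requires finite values, unique non-empty sample and feature IDs,
#' and -- when `normalized` is `TRUE` -- every feature lying in \[0, 1\].
#'
#' @slot normalized logical scalar; `TRUE` after [minMaxNormalize()].
#' @seealso [ExprMatrix()], [exprValues()], [minMaxNormalize()]
#' @aliases ExprMatrix-class
#' @exportClass ExprMatrix
setClass("ExprMatrix",
  contains = "SummarizedExperiment",
  representation(normalized = "logical"),
  prototype(normalized = FALSE)
)

setValidity("ExprMatrix", function(object) {
  msg <- character()
  if (length(object@normalized) != 1L || is.na(object@normalized))
    msg <- c(msg, "'normalized' must be TRUE or FALSE")
  if (!"expr" %in% assayNames(object))
    msg <- c(msg, "assay 'expr' is missing")
  else {
    v <- assay(object, "expr")
    if (!is.numeric(v)) msg <- c(msg, "expression values must be numeric")
    else if (any(!is.finite(v)))
      msg <- c(msg, "expression values must be finite (no NA/NaN/Inf)")
    else if (isTRUE(object@normalized) &&
             (min(v) < 0 || max(v) > 1 + 1e-12))
      msg <- c(msg, "matrix is flagged normalized but values fall outside [0, 1]")
    rn <- rownames(object); cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn)))
      msg <- c(msg, "feature IDs must be unique non-empty strings")
    if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn)))
      msg <- c(msg, "sample IDs must be unique non-empty strings")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExprMatrix
#'
#' @param values numeric matrix, samples in rows and features in columns,
#'   with unique row (sample ID) and column (feature ID) names.
#' @param normalized logical; set `TRUE` only if each feature already lies in
#'   \[0, 1\] (e.g. values produced by [minMaxNormalize()]).
#' @return An [ExprMatrix-class] object.
#' @examples
#' x <- matrix(runif(12), 4, 3,
#'             dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
#' em <- ExprMatrix(x)
#' dim(em)          # 3 features x 4 samples (SummarizedExperiment layout)
#' dim(exprValues(em))  # 4 x 3, samples x features
#' @export
ExprMatrix <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs sample IDs as rownames and feature IDs as colnames")
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = list(expr = t(values)))
  new("ExprMatrix", se, normalized = isTRUE(normalized))
}

#' Concrete autoencoder configuration
#'
#' Hyperparameters of a single concrete-autoencoder run.  Defaults follow the
#' settings that worked best on pan-cancer lncRNA expression: a decoder with
#' two 300-node hidden layers, leaky-ReLU slope 0.1, 10% dropout, 300 epochs
#' of Adam at learning rate 0.002, and an exponential temperature schedule
#' from 10 down to 0.1.  The default minibatch size of 16 keeps the number
#' of optimizer updates (which bounds how far the selection logits can move,
#' hence whether the selector can harden) in the thousands even on
#' few-hundred-sample cohorts; see the package vignette.
#'
#' @slot k integer; number of selector nodes = number of features selected.
#' @slot hiddenSizes integer vector; decoder hidden layer widths.
#' @slot leakyReluSlope numeric; negative-part slope of the decoder
#'   activation.
#' @slot dropoutRate numeric in \[0, 1); dropout applied after each hidden
#'   layer during training.
#' @slot epochs integer; training epochs (temperature is annealed per epoch).
#' @slot learningRate numeric; Adam step size.
#' @slot tStart,tEnd numeric; start and end temperatures, `0 < tEnd < tStart`.
#' @slot batchSize integer; minibatch size.
#' @slot seed integer; seed controlling every stochastic element of the run.
#' @aliases CAEConfig-class
#' @seealso [caeConfig()], [trainCAE()]
#' @exportClass CAEConfig
setClass("CAEConfig", representation(
  k = "integer", hiddenSizes = "integer", leakyReluSlope = "numeric",
  dropoutRate = "numeric", epochs = "integer", learningRate = "numeric",
  tStart = "numeric", tEnd = "numeric", batchSize = "integer",
  seed = "integer"
))

setValidity("CAEConfig", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(object@hiddenSizes) < 1L || any(object@hiddenSizes < 1L))
    msg <- c(msg, "hiddenSizes must be positive integers")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (!(object@tEnd > 0 && object@tEnd < object@tStart))
    msg <- c(msg, "temperatures must satisfy 0 < tEnd < tStart")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname CAEConfig-class
#' @param k,hiddenSizes,leakyReluSlope,dropoutRate,epochs,learningRate See
#'   the slot documentation above.
#' @param tStart,tEnd,batchSize,seed See the slot documentation above.
#' @return `caeConfig()` returns a validated `CAEConfig`.
#' @examples
#' caeConfig(k = 10, epochs = 50, seed = 1)
#' @export
caeConfig <- function(k, hiddenSizes = c(300L, 300L), leakyReluSlope = 0.1,
                      dropoutRate = 0.1, epochs = 300L, learningRate = 0.002,
                      tStart = 10, tEnd = 0.1, batchSize = 16L, seed = 1L) {
  new("CAEConfig",
      k = as.integer(k), hiddenSizes = as.integer(hiddenSizes),
      leakyReluSlope = as.numeric(leakyReluSlope),
      dropoutRate = as.numeric(dropoutRate), epochs = as.integer(epochs),
      learningRate = as.numeric(learningRate), tStart = as.numeric(tStart),
      tEnd = as.numeric(tEnd), batchSize = as.integer(batchSize),
      seed = as.integer(seed))
}

#' Result of a single concrete-autoencoder run
#'
#' @slot selectedUnique character; deduplicated selected feature IDs
#'   (at most `k`).
#' @slot nodePicks character of length `k`; the argmax feature of each
#'   selector node (repeats possible).
#' @slot trace data.frame with one row per epoch: `epoch`, `temperature`,
#'   `mean_max_prob`, `train_loss`, `val_loss` (the characteristic trace).
#' @slot valMSE numeric; reconstruction MSE on the held-out split using hard
#'   one-hot selection.
#' @slot config the [CAEConfig-class] used.
#' @slot seed integer seed of this run.
#' @slot selectorLogits k-by-n matrix of trained selection logits (may be
#'   empty for runs re-read from JSON).
#' @slot decoder list of trained decoder weights (may be empty for runs
#'   re-read from JSON).
#' @slot featureIDs character; the feature space the run was trained on.
#' @aliases CAERun-class
#' @seealso [trainCAE()], [selectedFeatures()], [caeTrace()]
#' @exportClass CAERun
setClass("CAERun", representation(
  selectedUnique = "character", nodePicks = "character",
  trace = "data.frame", valMSE = "numeric", config = "CAEConfig",
  seed = "integer", selectorLogits = "matrix", decoder = "list",
  featureIDs = "character"
))

setValidity("CAERun", function(object) {
  msg <- character()
  if (!setequal(object@selectedUnique, unique(object@nodePicks)))
    msg <- c(msg, "selectedUnique must equal the deduplicated nodePicks")
  if (length(object@selectedUnique) > object@config@k)
    msg <- c(msg, "more unique features than selector nodes")
  need <- c("epoch", "temperature", "mean_max_prob", "train_loss", "val_loss")
  if (!all(need %in% names(object@trace)))
    msg <- c(msg, "trace lacks required columns")
  else if (nrow(object@trace) && is.unsorted(-object@trace$temperature))
    msg <- c(msg, "temperature must be non-increasing across epochs")
  if (length(msg)) msg else TRUE
})

#' Cross-run feature frequency table
#'
#' Counts, for each feature ever selected, the number of runs whose
#' deduplicated selection contains it.
#'
#' @slot counts named integer vector, one entry per distinct selected
#'   feature; every count lies in `[1, totalRuns]`.
#' @slot totalRuns integer; number of runs aggregated.
#' @aliases FrequencyTable-class
#' @seealso [frequencyTable()], [topStableFeatures()]
#' @exportClass FrequencyTable
setClass("FrequencyTable",
  representation(counts = "integer", totalRuns = "integer"))

setValidity("FrequencyTable", function(object) {
  msg <- character()
  if (is.null(names(object@counts)) || anyDuplicated(names(object@counts)))
    msg <- c(msg, "counts must be uniquely named by feature ID")
  if (length(object@counts) &&
      (min(object@counts) < 1L || max(object@counts) > object@totalRuns))
    msg <- c(msg, "every count must lie in [1, totalRuns]")
  if (length(msg)) msg else TRUE
})

#' Ranked stable feature set
#'
#' The Top-N features of a [FrequencyTable-class], ordered by descending
#' cross-run frequency with ties broken by feature ID (ascending), so the
#' ranking is deterministic.
#'
#' @slot ranked data.frame with columns `feature_id`, `frequency`
#'   (non-increasing).
#' @slot nRequested integer; the N that was asked for.
#' @slot tieRule character; documentation of the tie-break.
#' @aliases StableFeatureSet-class
#' @seealso [topStableFeatures()]
#' @exportClass StableFeatureSet
setClass("StableFeatureSet", representation(
  ranked = "data.frame", nRequested = "integer", tieRule = "character"))

setValidity("StableFeatureSet", function(object) {
  msg <- character()
  if (!all(c("feature_id", "frequency") %in% names(object@ranked)))
    msg <- c(msg, "ranked needs columns feature_id, frequency")
  else if (nrow(object@ranked) > 1L &&
           is.unsorted(-object@ranked$frequency))
    msg <- c(msg, "frequencies must be non-increasing")
  if (length(msg)) msg else TRUE
})
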