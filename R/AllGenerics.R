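#' Accessors for mrcae objects
#'
#' Small generic accessors: `exprValues()` returns the samples-by-features
#' numeric matrix of an [ExprMatrix-class]; `sampleIDs()` and `featureIDs()`
#' its dimension names; `isNormalized()` the normalization flag;
#' `selectedFeatures()` the deduplicated selection of a [CAERun-class];
#' `nodePicks()` the per-node argmax picks; `caeTrace()` the per-epoch
#' characteristic trace; `valMSE()` the held-out hard-selection MSE;
#' `featureFrequencies()` the named count vector of a
#' [FrequencyTable-class]; `totalRuns()` its run count; `rankedFeatures()`
#' the ranked data.frame of a [StableFeatureSet-class].
#'
#' @param x an object of the documented class.
#' @return See each accessor's description.
#' @name accessors
#' @examples
#' m <- matrix(runif(20), 5, 4,
#'             dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
#' em <- ExprMatrix(m)
#' sampleIDs(em)
#' featureIDs(em)
#' isNormalized(em)
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("nodePicks", function(x) standardGeneric("nodePicks"))
#' @rdname accessors
#' @export
setGeneric("caeTrace", function(x) standardGeneric("caeTrace"))
#' @rdname accessors
#' @export
setGeneric("valMSE", function(x) standardGeneric("valMSE"))
#' @rdname accessors
#' @export
setGeneric("featureFrequencies",
           function(x) standardGeneric("featureFrequencies"))
#' @rdname accessors
#' @export
setGeneric("totalRuns", function(x) standardGeneric("totalRuns"))
#' @rdname accessors
#' @export
setGeneric("rankedFeatures", function(x) standardGeneric("rankedFeatures"))

#' @rdname accessors
setMethod("exprValues", "ExprMatrix", function(x) t(assay(x, "expr")))
#' @rdname accessors
setMethod("sampleIDs", "ExprMatrix", function(x) colnames(x))
#' @rdname accessors
setMethod("featureIDs", "ExprMatrix", function(x) rownames(x))
#' @rdname accessors
setMethod("isNormalized", "ExprMatrix", function(x) x@normalized)

#' @rdname accessors
setMethod("selectedFeatures", "CAERun", function(x) x@selectedUnique)
#' @rdname accessors
setMethod("nodePicks", "CAERun", function(x) x@nodePicks)
#' @rdname accessors
setMethod("caeTrace", "CAERun", function(x) x@trace)
#' @rdname accessors
setMethod("valMSE", "CAERun", function(x) x@valMSE)

#' @rdname accessors
setMethod("featureFrequencies", "FrequencyTable", function(x) x@counts)
#' @rdname accessors
setMethod("totalRuns", "FrequencyTable", function(x) x@totalRuns)
#' @rdname accessors
setMethod("rankedFeatures", "StableFeatureSet", function(x) x@ranked)

setMethod("show", "ExprMatrix", function(object) {
  cat(sprintf("ExprMatrix: %d samples x %d features (%s)\n",
              ncol(object), nrow(object),
              if (object@normalized) "min-max normalized" else "raw"))
  callNextMethod()
})

setMethod("show", "CAEConfig", function(object) {
  cat("CAEConfig\n")
  cat(sprintf("  k = %d selector nodes; decoder hidden: %s; leaky ReLU %.3g; dropout %.0f%%\n",
              object@k, paste(object@hiddenSizes, collapse = "-"),
              object@leakyReluSlope, 100 * object@dropoutRate))
  cat(sprintf("  %d epochs, Adam lr %.4g, batch %d, temperature %.3g -> %.3g, seed %d\n",
              object@epochs, object@learningRate, object@batchSize,
              object@tStart, object@tEnd, object@seed))
})

setMethod("show", "CAERun", function(object) {
  tr <- object@trace
  cat(sprintf("CAERun (seed %d): %d/%d unique features selected\n",
              object@seed, length(object@selectedUnique), object@config@k))
  if (nrow(tr)) {
    last <- tr[nrow(tr), ]
    cat(sprintf("  final epoch %d: T = %.3g, mean-max prob = %.3f, train loss = %.4g, val loss = %.4g\n",
                last$epoch, last$temperature, last$mean_max_prob,
                last$train_loss, last$val_loss))
  }
  cat(sprintf("  held-out hard-selection MSE: %.4g\n", object@valMSE))
})

setMethod("show", "FrequencyTable", function(object) {
  cat(sprintf("FrequencyTable: %d distinct features over %d runs (frequency %s)\n",
              length(object@counts), object@totalRuns,
              if (length(object@counts))
                paste(range(object@counts), collapse = "-") else "-"))
})

setMethod("show", "StableFeatureSet", function(object) {
  cat(sprintf("StableFeatureSet: top %d of %d requested (ties: %s)\n",
              nrow(object@ranked), object@nRequested, object@tieRule))
  print(head(object@ranked, 10), row.names = FALSE)
  if (nrow(object@ranked) > 10) cat("  ...\n")
})
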