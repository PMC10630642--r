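# Generics and accessors. Slot access from user code goes through these.

#' @export
setGeneric("boxCoords", function(x) standardGeneric("boxCoords"))
#' @export
setGeneric("boxArea", function(x) standardGeneric("boxArea"))
#' @export
setGeneric("filterTrace", function(x) standardGeneric("filterTrace"))
#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @export
setGeneric("featureSpans", function(x) standardGeneric("featureSpans"))
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @export
setGeneric("classMetrics", function(x, ...) standardGeneric("classMetrics"))
#' @export
setGeneric("entropyScores", function(x) standardGeneric("entropyScores"))
#' @export
setGeneric("selectedIndices", function(x) standardGeneric("selectedIndices"))
#' @export
setGeneric("applySelector", function(x, m) standardGeneric("applySelector"))
#' @export
setGeneric("nWeightLayers", function(x) standardGeneric("nWeightLayers"))
#' @export
setGeneric("nPoolStages", function(x) standardGeneric("nPoolStages"))
#' @export
setGeneric("paramCount", function(x) standardGeneric("paramCount"))
#' @export
setGeneric("paramChecksum", function(x) standardGeneric("paramChecksum"))
#' @export
setGeneric("layerInventory", function(x) standardGeneric("layerInventory"))
#' @export
setGeneric("extractDeepFeatures", function(x, images, ...)
  standardGeneric("extractDeepFeatures"))
#' @export
setGeneric("predictHead", function(x, m) standardGeneric("predictHead"))

#' Accessors for pipeline result objects
#'
#' \code{boxCoords} returns the 0-based half-open coordinates of a
#' [BoundingBox-class] as a named integer vector; \code{boxArea} its pixel
#' area. \code{filterTrace}/\code{stopReason} expose the per-iteration
#' record of a [FilterDiagnostics-class]. \code{featureValues} and
#' \code{featureSpans} expose a [FeatureVector-class]'s data and layout
#' manifest. \code{counts} returns the four cells of a
#' [ConfusionMatrix-class]. \code{entropyScores}/\code{selectedIndices}
#' expose an [EntropySelector-class] fit.
#'
#' @param x the object.
#' @return See details; plain base-R vectors and data frames.
#' @name accessors
#' @aliases boxCoords boxArea filterTrace stopReason featureValues
#'   featureSpans counts entropyScores selectedIndices
NULL

#' @rdname accessors
#' @export
setMethod("boxCoords", "BoundingBox", function(x)
  c(rowStart = x@rowStart, rowStop = x@rowStop,
    colStart = x@colStart, colStop = x@colStop))

#' @rdname accessors
#' @export
setMethod("boxArea", "BoundingBox", function(x)
  as.numeric(x@rowStop - x@rowStart) * as.numeric(x@colStop - x@colStart))

#' @rdname accessors
#' @export
setMethod("filterTrace", "FilterDiagnostics", function(x) x@trace)

#' @rdname accessors
#' @export
setMethod("stopReason", "FilterDiagnostics", function(x) x@stopReason)

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureVector", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("featureSpans", "FeatureVector", function(x) x@spans)

#' @rdname accessors
#' @export
setMethod("counts", "ConfusionMatrix", function(x)
  c(TP = x@tp, FN = x@fn, FP = x@fp, TN = x@tn))

#' @rdname accessors
#' @export
setMethod("entropyScores", "EntropySelector", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("selectedIndices", "EntropySelector", function(x) x@indices)

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox rows [%d, %d) x cols [%d, %d)  (%d x %d px)\n",
              object@rowStart, object@rowStop, object@colStart, object@colStop,
              object@rowStop - object@rowStart,
              object@colStop - object@colStart))
})

setMethod("show", "FilterDiagnostics", function(object) {
  n <- nrow(object@trace)
  cat(sprintf("FilterDiagnostics: %d iteration%s, stopped by '%s'\n",
              n, if (n == 1L) "" else "s", object@stopReason))
  if (n > 0L) {
    last <- object@trace[n, ]
    cat(sprintf("  final excess kurtosis %.4g, rho_G %.4g\n",
                last$k, last$rho_G))
  }
})

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf("FeatureVector of length %d\n", length(object@values)))
  for (nm in names(object@spans)) {
    sp <- object@spans[[nm]]
    cat(sprintf("  %-5s [%5d, %5d)  (%d features)\n",
                nm, sp[1L], sp[2L], sp[2L] - sp[1L]))
  }
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (positive class: melanoma)\n")
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2L, 2L,
              byrow = TRUE,
              dimnames = list(c("true melanoma", "true non_melanoma"),
                              c("pred melanoma", "pred non_melanoma")))
  print(m)
})

setMethod("show", "EntropySelector", function(object) {
  cat(sprintf(
    "EntropySelector: %d of %d features kept (%d-bin entropy, bits)\n",
    length(object@indices), length(object@scores), object@nBins))
})

setMethod("show", "VGGBackbone", function(object) {
  cat(sprintf(
    "VGGBackbone: %d weight layers (%d conv + %d FC), %d pooling stages\n",
    nWeightLayers(object), length(unlist(object@spec$convBlocks)),
    length(object@spec$fc), nPoolStages(object)))
  cat(sprintf("  input %dx%dx3, feature tap FC1 (%d-d, post-ReLU), seed %d\n",
              object@spec$inputSize, object@spec$inputSize,
              object@spec$fc[1L], object@seed))
})

setMethod("show", "DermoHead", function(object) {
  cat(sprintf("DermoHead '%s' (positive class: %s)\n",
              object@type, object@levels[1L]))
})
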