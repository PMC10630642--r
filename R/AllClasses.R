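# S4 containers for the pipeline's central objects. Images stay plain
# numeric matrices in [0,1]; these classes hold derived, structured results.

#' Axis-parallel lesion bounding box
#'
#' Pixel coordinates are 0-based, half-open intervals \code{[start, stop)} on
#' each axis, so \code{rowStop - rowStart} is the box height in pixels.
#'
#' @slot rowStart,rowStop,colStart,colStop integer scalars, 0-based half-open.
#' @seealso [fbbDetect], [cropBox], [boxIoU]
#' @exportClass BoundingBox
setClass("BoundingBox",
  representation(rowStart = "integer", rowStop = "integer",
                 colStart = "integer", colStop = "integer"),
  validity = function(object) {
    v <- c(object@rowStart, object@rowStop, object@colStart, object@colStop)
    if (length(v) != 4L || anyNA(v)) return("all four coordinates must be set")
    if (object@rowStart < 0L || object@colStart < 0L)
      return("start coordinates must be >= 0")
    if (object@rowStop <= object@rowStart || object@colStop <= object@colStart)
      return("stop must exceed start on both axes")
    TRUE
  })

#' Per-iteration trace of the modified anisotropic diffusion filter
#'
#' One row per executed iteration: \code{iter}, excess kurtosis \code{k} of
#' the multiplicative residual, image-intensity correlation \code{rho_I}
#' (noisy input vs current estimate), noise-intensity correlation
#' \code{rho_G} (estimate vs residual), and the residual mean
#' \code{mean_mu}. \code{stopReason} records which rule ended the loop.
#'
#' @slot trace data.frame with columns iter, k, rho_I, rho_G, mean_mu.
#' @slot stopReason one of \code{"kurtosis"}, \code{"correlation_min"},
#'   \code{"max_iters"}.
#' @seealso [madfFilter]
#' @exportClass FilterDiagnostics
setClass("FilterDiagnostics",
  representation(trace = "data.frame", stopReason = "character"),
  validity = function(object) {
    need <- c("iter", "k", "rho_I", "rho_G", "mean_mu")
    if (!all(need %in% names(object@trace)))
      return(paste("trace must have columns", paste(need, collapse = ", ")))
    if (!object@stopReason %in% c("kurtosis", "correlation_min", "max_iters"))
      return("unknown stopReason")
    TRUE
  })

#' Named fixed-length feature vector with a component-layout manifest
#'
#' \code{spans} maps each named component (e.g. \code{hog}, \code{surf},
#' \code{lbp}, \code{cnn}) to a 0-based half-open index interval
#' \code{c(start, stop)} into \code{values}. Spans must be disjoint and
#' cover the vector exactly.
#'
#' @slot values numeric vector.
#' @slot spans named list of length-2 integer vectors.
#' @seealso [fuseHFE], [fuseAll], [featureSpans]
#' @exportClass FeatureVector
setClass("FeatureVector",
  representation(values = "numeric", spans = "list"),
  validity = function(object) {
    if (length(object@spans) == 0L) return("spans must be non-empty")
    if (is.null(names(object@spans)) || any(names(object@spans) == ""))
      return("spans must be named")
    iv <- do.call(rbind, lapply(object@spans, as.integer))
    if (ncol(iv) != 2L) return("each span must be c(start, stop)")
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (iv[1L, 1L] != 0L || iv[nrow(iv), 2L] != length(object@values))
      return("spans must cover [0, length(values))")
    if (nrow(iv) > 1L && any(iv[-1L, 1L] != iv[-nrow(iv), 2L]))
      return("spans must be disjoint and contiguous")
    TRUE
  })

#' Binary confusion matrix with melanoma as the positive class
#'
#' @slot tp,fn,fp,tn nonnegative integer counts; \code{tp + fn} is the
#'   number of true melanoma samples.
#' @seealso [confusionCounts], [classMetrics]
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(tp = "numeric", fn = "numeric", fp = "numeric", tn = "numeric"),
  validity = function(object) {
    v <- c(object@tp, object@fn, object@fp, object@tn)
    if (anyNA(v) || any(v < 0)) return("counts must be nonnegative")
    if (any(v != round(v))) return("counts must be whole numbers")
    TRUE
  })

#' Entropy-based feature selector
#'
#' Fitted on a training feature matrix: every column is scored by the
#' Shannon entropy (bits) of its equal-width histogram over the observed
#' training range; the \code{k} highest-entropy columns are retained, ties
#' broken toward the lower column index. \code{indices} are stored sorted
#' ascending (1-based) and reused verbatim on test data.
#'
#' @slot scores per-column entropy in bits.
#' @slot indices selected column indices, strictly increasing, 1-based.
#' @slot edges per-selected-column histogram bin edges learned on training
#'   data (list parallel to \code{indices}).
#' @slot nBins,k integer parameters of the fit.
#' @seealso [fitEntropySelector], [applySelector]
#' @exportClass EntropySelector
setClass("EntropySelector",
  representation(scores = "numeric", indices = "integer", edges = "list",
                 nBins = "integer", k = "integer"),
  validity = function(object) {
    if (length(object@indices) != min(object@k, length(object@scores)))
      return("selected length must be min(k, dimension)")
    if (is.unsorted(object@indices, strictly = TRUE))
      return("indices must be strictly increasing")
    if (length(object@indices) && (min(object@indices) < 1L ||
        max(object@indices) > length(object@scores)))
      return("indices out of range")
    TRUE
  })

#' VGG19-topology feature backbone
#'
#' Holds the layer plan (16 convolution layers in 5 blocks of depths
#' 64/64, 128/128, 256 x 4, 512 x 4, 512 x 4, each block followed by 2x2
#' max-pooling, then 3 fully connected layers 4096/4096/nClasses) together
#' with the seed that deterministically generates its weights. The native
#' parameter store is rebuilt on demand from the seed, so the object
#' serializes losslessly.
#'
#' @slot spec list describing the topology (see [backboneSpec]).
#' @slot seed integer weight-initialization seed.
#' @slot ptr external pointer to the native parameter store (may be stale
#'   after deserialization; rebuilt lazily).
#' @seealso [buildBackbone], [extractDeepFeatures], [layerInventory]
#' @exportClass VGGBackbone
setClass("VGGBackbone",
  representation(spec = "list", seed = "integer", ptr = "ANY"))

#' Trained classifier head
#'
#' Wraps one of the pluggable heads (\code{mlp}, \code{dt}, \code{rf},
#' \code{knn}, \code{svm}) together with the feature standardization
#' (training-set center/scale) applied before fitting.
#'
#' @slot type head identifier.
#' @slot fit the underlying fitted model object.
#' @slot levels class labels, positive class first.
#' @slot center,scale per-feature standardization learned on training data.
#' @slot seed integer training seed.
#' @seealso [trainHead], [predictHead]
#' @exportClass DermoHead
setClass("DermoHead",
  representation(type = "character", fit = "ANY", levels = "character",
                 center = "numeric", scale = "numeric", seed = "integer"))
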