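# VGG19-topology feature backbone: the deep branch of the pipeline taps
# the first fully connected layer (post-ReLU) for 4096 features per
# image. Weights are seeded random (He initialization), which preserves
# every dimensional and determinism contract; externally supplied
# weights can be plugged in with loadBackboneWeights().

#' Backbone topology specification
#'
#' VGG19: five convolution blocks of depths (64, 64), (128, 128),
#' (256 x 4), (512 x 4), (512 x 4) — 16 convolution layers, each block
#' followed by 2 x 2 max-pooling — and three fully connected layers
#' (4096, 4096, nClasses), 19 weight layers in total. ReLU activations
#' throughout; dropout rate and L2 penalty are carried for the training
#' configuration but do not affect feature extraction.
#'
#' @param nClasses output width of the last fully connected layer.
#' @param inputSize input side in pixels (must be divisible by 32).
#' @param dropout FC dropout rate (topology metadata).
#' @param l2 L2 penalty coefficient (topology metadata).
#' @param seed weight-initialization seed.
#' @return a \code{backboneSpec} list.
#' @export
backboneSpec <- function(nClasses = 2L, inputSize = 224L, dropout = 0.5,
                         l2 = 5e-4, seed = 1L) {
  if (inputSize %% 32L != 0L || inputSize < 32L)
    stop("inputSize must be a positive multiple of 32")
  convBlocks <- list(c(64L, 64L), c(128L, 128L), rep(256L, 4L),
                     rep(512L, 4L), rep(512L, 4L))
  structure(list(convBlocks = convBlocks,
                 fc = c(4096L, 4096L, as.integer(nClasses)),
                 inputSize = as.integer(inputSize), dropout = dropout,
                 l2 = l2, seed = as.integer(seed)),
            class = "backboneSpec")
}

specPlan <- function(spec) {
  unlist(lapply(spec$convBlocks, function(b) c(b, -1L)))
}

#' Build the backbone with seeded deterministic weights
#'
#' Constructs the native parameter store from the spec's seed (He-scaled
#' Gaussian weights, zero biases). The same seed always yields the same
#' parameters, verifiable with [paramChecksum].
#'
#' @param spec a [backboneSpec].
#' @return a [VGGBackbone-class].
#' @export
buildBackbone <- function(spec = backboneSpec()) {
  if (!inherits(spec, "backboneSpec")) stop("malformed backbone spec")
  ptr <- .cnn_build(specPlan(spec), spec$fc, spec$inputSize, spec$seed)
  new("VGGBackbone", spec = unclass(spec), seed = spec$seed, ptr = ptr)
}

# The external pointer dies on serialization; rebuild from the seed.
backbonePtr <- function(x) {
  if (!.cnn_valid(x@ptr)) {
    sp <- x@spec
    x@ptr <- .cnn_build(specPlan(sp), sp$fc, sp$inputSize, x@seed)
  }
  x@ptr
}

#' @describeIn buildBackbone number of weight layers (16 conv + 3 FC = 19).
#' @param x a [VGGBackbone-class].
#' @export
setMethod("nWeightLayers", "VGGBackbone", function(x)
  length(unlist(x@spec$convBlocks)) + length(x@spec$fc))

#' @describeIn buildBackbone number of max-pooling stages (5).
#' @export
setMethod("nPoolStages", "VGGBackbone", function(x)
  length(x@spec$convBlocks))

#' @describeIn buildBackbone total trainable parameter count.
#' @export
setMethod("paramCount", "VGGBackbone", function(x)
  .cnn_param_count(backbonePtr(x)))

#' @describeIn buildBackbone deterministic checksum (sum of all weights).
#' @export
setMethod("paramChecksum", "VGGBackbone", function(x)
  .cnn_checksum(backbonePtr(x)))

#' @describeIn buildBackbone per-layer inventory as a data.frame
#'   (\code{layer, type, output_channels, params}).
#' @export
setMethod("layerInventory", "VGGBackbone", function(x) {
  convs <- unlist(x@spec$convBlocks)
  inC <- 3L
  rows <- list()
  for (i in seq_along(convs)) {
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("conv%d", i), type = "conv3x3",
      output_channels = convs[i],
      params = convs[i] * (inC * 9L + 1L))
    inC <- convs[i]
  }
  side <- x@spec$inputSize %/% 2L^length(x@spec$convBlocks)
  fin <- side * side * inC
  for (j in seq_along(x@spec$fc)) {
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("fc%d", j), type = "dense",
      output_channels = x@spec$fc[j],
      params = x@spec$fc[j] * (fin + 1L))
    fin <- x@spec$fc[j]
  }
  do.call(rbind, rows)
})

#' Load externally supplied weights into a backbone
#'
#' Replaces the seeded random parameters of selected layers with supplied
#' matrices — the hook for plugging in pretrained VGG19 weights. Weight
#' layers are numbered 1..19: convolutions 1..16 in network order (each a
#' \code{(inChannels * 9) x outChannels} matrix whose rows index the 3 x 3
#' patch unrolled as channel-major, row-offset, column-offset), then the
#' three fully connected layers.
#'
#' Note that loaded weights live only in the native store: after
#' serialization the backbone reseeds to its random initialization, so
#' reload weights after \code{readRDS()}.
#'
#' @param backbone a [VGGBackbone-class].
#' @param weights named or indexed list; element \code{i} is either a
#'   matrix (zero biases) or a \code{list(W = matrix, b = vector)} for
#'   weight layer \code{i}. \code{NULL} elements are skipped.
#' @return the backbone, invisibly (modified in place).
#' @export
loadBackboneWeights <- function(backbone, weights) {
  ptr <- backbonePtr(backbone)
  for (i in seq_along(weights)) {
    el <- weights[[i]]
    if (is.null(el)) next
    if (is.matrix(el)) el <- list(W = el, b = numeric(ncol(el)))
    .cnn_set_layer(ptr, i, el$W, el$b)
  }
  invisible(backbone)
}

#' Extract 4096-d deep features
#'
#' Resizes each grayscale image to the backbone input size, replicates it
#' to 3 channels, centers it, and runs the convolutional stack; the
#' returned features are the first fully connected layer's output after
#' ReLU, hence nonnegative.
#'
#' @param x a [VGGBackbone-class].
#' @param images a single gray matrix, a list of gray matrices, or a
#'   \code{h x w x 3} RGB array.
#' @param ... unused.
#' @return numeric matrix, one row per image, 4096 columns.
#' @export
setMethod("extractDeepFeatures", "VGGBackbone", function(x, images, ...) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  ptr <- backbonePtr(x)
  sz <- x@spec$inputSize
  out <- matrix(0, length(images), x@spec$fc[1L])
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (is.matrix(im)) {
      m <- clip01(resizeGray(im, sz, sz))
      a <- array(rep(m, 3L), dim = c(sz, sz, 3L))
    } else if (length(dim(im)) == 3L && dim(im)[3L] == 3L) {
      a <- array(0, dim = c(sz, sz, 3L))
      for (ch in 1:3) a[, , ch] <- clip01(resizeGray(im[, , ch], sz, sz))
    } else stop("unsupported input shape for image ", i)
    out[i, ] <- .cnn_forward(ptr, a)
  }
  out
})
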