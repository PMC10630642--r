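# Fusion of the hybrid (3852) and deep (4096) feature vectors into 7948
# features, and entropy-based selection of the top 1280.

#' Fuse hybrid and deep feature vectors
#'
#' Lossless concatenation (HFE then CNN) into the 7948-long fused vector
#' with a span manifest.
#'
#' @param hfe length-3852 hybrid vector or the [FeatureVector-class] from
#'   [fuseHFE] / [hfeFeatures].
#' @param cnn length-4096 deep feature vector.
#' @return a [FeatureVector-class] of length 7948 with spans \code{hfe}
#'   and \code{cnn}.
#' @export
fuseAll <- function(hfe, cnn) {
  h <- if (is(hfe, "FeatureVector")) featureValues(hfe) else as.numeric(hfe)
  if (length(h) != 3852L) stop("hfe component must have length 3852")
  if (length(cnn) != 4096L) stop("cnn component must have length 4096")
  new("FeatureVector", values = c(h, as.numeric(cnn)),
      spans = list(hfe = c(0L, 3852L), cnn = c(3852L, 7948L)))
}

#' Shannon entropy of a feature column
#'
#' Equal-width histogram with \code{nBins} bins over the observed
#' \code{[min, max]} range, then \eqn{H = -\sum p \log_2 p} over nonempty
#' bins (bits). A constant column has a single occupied bin and entropy 0.
#'
#' @param values numeric vector, at least 2 samples.
#' @param nBins number of bins, >= 2.
#' @return entropy in bits; attribute \code{"edges"} holds the bin edges.
#' @export
featureEntropy <- function(values, nBins = 10L) {
  x <- as.numeric(values)
  if (length(x) < 2L) stop("need at least 2 samples")
  if (nBins < 2L) stop("nBins must be >= 2")
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    return(structure(0, edges = c(lo, hi)))
  }
  edges <- seq(lo, hi, length.out = nBins + 1L)
  idx <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              nBins)
  p <- tabulate(idx, nbins = nBins) / length(x)
  p <- p[p > 0]
  structure(-sum(p * log2(p)), edges = edges)
}

#' Fit the entropy-based feature selector
#'
#' Scores every column of the training matrix with [featureEntropy] and
#' keeps the \code{k} highest-entropy columns; ties break toward the
#' lower column index. Bin edges are learned on the training data only
#' and stored; at prediction time the selection indices are reused
#' verbatim, so no information flows from test data into the selector.
#'
#' @param m training feature matrix (samples x features), >= 2 rows.
#' @param k number of columns to keep (default 1280).
#' @param nBins histogram bins per feature (default 10).
#' @return an [EntropySelector-class].
#' @export
fitEntropySelector <- function(m, k = 1280L, nBins = 10L) {
  if (!is.matrix(m) || nrow(m) < 2L)
    stop("need a matrix with at least 2 training samples")
  if (k > ncol(m)) stop("k exceeds the feature dimension")
  scored <- lapply(seq_len(ncol(m)), function(j)
    featureEntropy(m[, j], nBins = nBins))
  scores <- vapply(scored, as.numeric, numeric(1))
  ord <- order(-scores, seq_along(scores))
  idx <- sort(ord[seq_len(k)])
  new("EntropySelector", scores = scores, indices = as.integer(idx),
      edges = lapply(scored[idx], attr, "edges"),
      nBins = as.integer(nBins), k = as.integer(k))
}

#' @describeIn fitEntropySelector apply a fitted selector: subset the
#'   columns of \code{m} at the stored indices (train and test use the
#'   same indices).
#' @param x a fitted [EntropySelector-class].
#' @export
setMethod("applySelector", "EntropySelector", function(x, m) {
  if (is(m, "FeatureVector")) m <- matrix(featureValues(m), nrow = 1L)
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  if (ncol(m) != length(x@scores))
    stop("dimension mismatch: selector was fitted on ", length(x@scores),
         " features, got ", ncol(m))
  m[, x@indices, drop = FALSE]
})
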