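# Fast bounding box: unsupervised, linear-time lesion localization. The
# below-median darkness of each pixel is projected onto the two axes; on
# each axis the shortest interval holding a fraction tau of the total
# darkness mass brackets the lesion.

#' Below-median darkness map
#'
#' \eqn{d = \max(0, m - I)} with \eqn{m} the global median intensity:
#' only pixels darker than typical skin contribute mass, which makes the
#' projection robust to illumination and residual speckle.
#'
#' @param image gray matrix in \code{[0, 1]}.
#' @return nonnegative matrix of the same shape.
#' @export
darknessMap <- function(image) {
  assertGray(image)
  pmax(median(image) - image, 0)
}

#' Project a nonnegative field onto one axis
#'
#' Sums the field along the other axis and attaches prefix sums, the
#' structure the linear interval search runs on.
#'
#' @param d nonnegative matrix.
#' @param axis \code{"row"} or \code{"col"}.
#' @return list with \code{axis}, \code{mass}, \code{prefix} (cumulative,
#'   \code{prefix[length(mass)]} = total mass).
#' @export
axisProfile <- function(d, axis = c("row", "col")) {
  axis <- match.arg(axis)
  if (any(d < 0)) stop("field must be nonnegative")
  mass <- if (axis == "row") rowSums(d) else colSums(d)
  list(axis = axis, mass = mass, prefix = cumsum(mass))
}

#' Shortest interval holding a mass fraction
#'
#' Two-pointer linear scan over the prefix sums: returns the shortest
#' half-open interval \code{[start, stop)} (0-based) whose mass is at
#' least \code{tau} times the total; among equally short intervals the
#' smallest start wins.
#'
#' @param profile output of [axisProfile].
#' @param tau target mass fraction in \code{(0, 1]}.
#' @return integer \code{c(start, stop)}, 0-based half-open.
#' @export
smallestMassInterval <- function(profile, tau) {
  stopifnot(tau > 0, tau <= 1)
  mass <- profile$mass
  total <- profile$prefix[length(mass)]
  if (total <= 0) stop("zero total mass: no signal to bracket")
  target <- tau * total
  best <- c(0L, length(mass))
  bestLen <- length(mass) + 1L
  left <- 1L
  cur <- 0
  for (right in seq_along(mass)) {
    cur <- cur + mass[right]
    while (cur - mass[left] >= target) {
      cur <- cur - mass[left]
      left <- left + 1L
    }
    if (cur >= target && (right - left + 1L) < bestLen) {
      bestLen <- right - left + 1L
      best <- c(left - 1L, right)
    }
  }
  as.integer(best)
}

#' Fast bounding box around the lesion
#'
#' Runs [darknessMap], projects it on both axes with [axisProfile], and
#' brackets each axis with [smallestMassInterval]. Total work is linear in
#' the pixel count. Intended input is the MADF-filtered image.
#'
#' @param image gray matrix in \code{[0, 1]}.
#' @param tau mass fraction per axis, default 0.95.
#' @return a [BoundingBox-class].
#' @export
fbbDetect <- function(image, tau = 0.95) {
  d <- darknessMap(image)
  if (sum(d) <= 0) stop("no lesion detected: zero darkness mass")
  ri <- smallestMassInterval(axisProfile(d, "row"), tau)
  ci <- smallestMassInterval(axisProfile(d, "col"), tau)
  new("BoundingBox", rowStart = ri[1L], rowStop = ri[2L],
      colStart = ci[1L], colStop = ci[2L])
}

#' Crop an image to a bounding box with padding
#'
#' Expands the box by \code{pad} pixels on every side, clamps to the
#' frame, and returns the cropped patch (the input to feature extraction).
#'
#' @param image gray matrix.
#' @param box a [BoundingBox-class].
#' @param pad nonnegative integer padding, default 2.
#' @return cropped gray matrix.
#' @export
cropBox <- function(image, box, pad = 2L) {
  r0 <- max(box@rowStart - pad, 0L) + 1L
  r1 <- min(box@rowStop + pad, nrow(image))
  c0 <- max(box@colStart - pad, 0L) + 1L
  c1 <- min(box@colStop + pad, ncol(image))
  image[r0:r1, c0:c1, drop = FALSE]
}

#' Intersection-over-union of two boxes
#'
#' @param a,b [BoundingBox-class] objects on the same image grid.
#' @return IoU in \code{[0, 1]}.
#' @export
boxIoU <- function(a, b) {
  ir <- max(0L, min(a@rowStop, b@rowStop) - max(a@rowStart, b@rowStart))
  ic <- max(0L, min(a@colStop, b@colStop) - max(a@colStart, b@colStart))
  inter <- as.numeric(ir) * as.numeric(ic)
  union <- boxArea(a) + boxArea(b) - inter
  if (union <= 0) return(0)
  inter / union
}

#' Tight bounding box of a logical mask
#'
#' @param mask logical matrix with at least one \code{TRUE}.
#' @return a [BoundingBox-class] (0-based half-open), the ground-truth
#'   reference for [boxIoU] checks.
#' @export
maskBBox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask")
  new("BoundingBox",
      rowStart = as.integer(min(w[, 1L]) - 1L),
      rowStop = as.integer(max(w[, 1L])),
      colStart = as.integer(min(w[, 2L]) - 1L),
      colStop = as.integer(max(w[, 2L])))
}
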