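# Hand-crafted descriptors: HOG (3780-d), uniform LBP histogram (59-d),
# SURF keypoint summary (13-d), concatenated into the 3852-d hybrid
# feature vector.

#' Image gradients with the [-1, 0, 1] kernel
#'
#' Central differences \eqn{g_x = I(x+1,y) - I(x-1,y)} (horizontal kernel
#' \code{K = [-1, 0, 1]}) and \eqn{g_y = I(x,y+1) - I(x,y-1)} with
#' replicated borders; magnitude \eqn{\sqrt{g_x^2 + g_y^2}} and unsigned
#' orientation \eqn{\theta = \arctan(g_y / g_x)} folded to
#' \code{[0, 180)} degrees. Here the x axis runs along columns and y along
#' rows, matching the \code{[row, col]} image convention.
#'
#' @param image gray matrix, at least 3 x 3.
#' @return list \code{gx}, \code{gy}, \code{magnitude}, \code{orientation}
#'   (degrees in \code{[0, 180)}).
#' @export
imageGradients <- function(image) {
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3x3")
  gx <- shiftPad(image, 0L, 1L) - shiftPad(image, 0L, -1L)
  gy <- shiftPad(image, 1L, 0L) - shiftPad(image, -1L, 0L)
  mag <- sqrt(gx^2 + gy^2)
  theta <- (atan2(gy, gx) * 180 / pi) %% 180
  list(gx = gx, gy = gy, magnitude = mag, orientation = theta)
}

#' HOG parameters
#'
#' The standard 64 x 128 detection-window geometry: 8 x 8 cells, 2 x 2
#' cell blocks at 1-cell stride, 9 unsigned orientation bins, L2 block
#' normalization — the unique standard configuration with a 3780-long
#' descriptor (15 x 7 blocks x 4 cells x 9 bins).
#'
#' @param windowRows,windowCols window size the input is resized to.
#' @param cell cell side in pixels.
#' @param blockCells block side in cells.
#' @param bins unsigned orientation bins over \code{[0, 180)}.
#' @param eps L2-normalization guard.
#' @return a \code{hogParams} list.
#' @export
hogParams <- function(windowRows = 128L, windowCols = 64L, cell = 8L,
                      blockCells = 2L, bins = 9L, eps = 1e-6) {
  structure(list(windowRows = as.integer(windowRows),
                 windowCols = as.integer(windowCols), cell = as.integer(cell),
                 blockCells = as.integer(blockCells), bins = as.integer(bins),
                 eps = eps),
            class = "hogParams")
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Resizes the input to the detection window, computes [imageGradients],
#' accumulates per-cell magnitude-weighted orientation histograms with
#' linear interpolation between the two nearest bins (bin centers at
#' \code{k * 20} degrees, wrapping at 180), L2-normalizes every 2 x 2-cell
#' block and concatenates blocks row-major. Default geometry yields a
#' 3780-long vector regardless of content.
#'
#' @param image gray matrix (resized internally to the window).
#' @param params a [hogParams].
#' @return numeric descriptor vector (length 3780 with defaults).
#' @export
hogDescriptor <- function(image, params = hogParams()) {
  p <- params
  img <- if (all(dim(image) == c(p$windowRows, p$windowCols))) image
         else resizeGray(image, p$windowRows, p$windowCols)
  g <- imageGradients(img)
  cellsR <- p$windowRows %/% p$cell
  cellsC <- p$windowCols %/% p$cell
  rows <- matrix(seq_len(p$windowRows), p$windowRows, p$windowCols)
  cols <- matrix(seq_len(p$windowCols), p$windowRows, p$windowCols,
                 byrow = TRUE)
  ci <- (rows - 1L) %/% p$cell
  cj <- (cols - 1L) %/% p$cell
  binWidth <- 180 / p$bins
  b <- g$orientation / binWidth
  k0 <- floor(b) %% p$bins
  frac <- b - floor(b)
  k1 <- (k0 + 1) %% p$bins
  cellBase <- ci + cellsR * cj
  idx <- c(cellBase + cellsR * cellsC * k0, cellBase + cellsR * cellsC * k1)
  wts <- c(g$magnitude * (1 - frac), g$magnitude * frac)
  hist <- numeric(cellsR * cellsC * p$bins)
  agg <- rowsum(as.numeric(wts), as.integer(idx))
  hist[as.integer(rownames(agg)) + 1L] <- agg
  dim(hist) <- c(cellsR, cellsC, p$bins)
  bc <- p$blockCells
  out <- vector("list", (cellsR - bc + 1L) * (cellsC - bc + 1L))
  n <- 0L
  for (by in seq_len(cellsR - bc + 1L)) {
    for (bx in seq_len(cellsC - bc + 1L)) {
      # cells row-major within the block, 9 bins per cell
      v <- as.numeric(aperm(
        hist[by:(by + bc - 1L), bx:(bx + bc - 1L), , drop = FALSE],
        c(3L, 2L, 1L)))
      n <- n + 1L
      out[[n]] <- v / sqrt(sum(v^2) + p$eps^2)
    }
  }
  unlist(out, use.names = FALSE)
}

#' Local binary pattern code of a 3 x 3 patch
#'
#' \eqn{l = \sum_{p=0}^{7} S(g_p - g_c) 2^p} with \eqn{S(x) = 1} iff
#' \eqn{x > 0} (strictly; ties code as 0) and neighbors ordered from the
#' top-left corner clockwise.
#'
#' @param patch 3 x 3 numeric matrix.
#' @return integer code in \code{[0, 255]}.
#' @export
lbpCode <- function(patch) {
  stopifnot(all(dim(patch) == c(3L, 3L)))
  nb <- c(patch[1L, 1L], patch[1L, 2L], patch[1L, 3L], patch[2L, 3L],
          patch[3L, 3L], patch[3L, 2L], patch[3L, 1L], patch[2L, 1L])
  sum(as.integer(nb > patch[2L, 2L]) * 2L^(0:7))
}

# Circular 0/1 transition count of an 8-bit code.
.lbpTransitions <- function(code) {
  bits <- as.integer(intToBits(code))[1:8]
  sum(abs(bits - bits[c(2:8, 1L)]))
}

# Map each of the 256 codes to a uniform-pattern bin: codes with <= 2
# circular transitions get bins 1..58 in ascending code order, the rest
# share the catch-all bin 59. Memoized at first use.
.lbpEnv <- new.env(parent = emptyenv())
lbpUniformMap <- function() {
  if (is.null(.lbpEnv$map)) {
    trans <- vapply(0:255, .lbpTransitions, numeric(1))
    uniform <- which(trans <= 2) - 1L
    map <- rep.int(59L, 256L)
    map[uniform + 1L] <- seq_along(uniform)
    .lbpEnv$map <- map
  }
  .lbpEnv$map
}

#' Uniform LBP histogram (59 bins)
#'
#' Computes the 8-neighbor LBP code of every interior pixel, maps codes to
#' the 58 uniform patterns (at most two circular 0/1 transitions) plus one
#' catch-all bin, and normalizes counts to frequencies. Because the code
#' uses strict comparisons of neighbor minus center, the histogram is
#' invariant to any global additive intensity shift.
#'
#' @param image gray matrix, at least 3 x 3.
#' @return numeric vector of length 59 summing to 1.
#' @export
lbpHistogram <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3L || nc < 3L) stop("image must be at least 3x3")
  ctr <- image[2:(nr - 1L), 2:(nc - 1L)]
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
               c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
  code <- matrix(0L, nr - 2L, nc - 2L)
  for (p in seq_along(offs)) {
    o <- offs[[p]]
    nbv <- image[(2:(nr - 1L)) + o[1L], (2:(nc - 1L)) + o[2L]]
    code <- code + (nbv > ctr) * 2L^(p - 1L)
  }
  bins <- lbpUniformMap()[as.integer(code) + 1L]
  tabulate(bins, nbins = 59L) / length(code)
}

# ---- SURF ----------------------------------------------------------------

# Integral image with a zero top row/left column, so the sum over rows
# r0..r1, cols c0..c1 is II[r1+1,c1+1] - II[r0,c1+1] - II[r1+1,c0] + II[r0,c0].
integralImage <- function(m) {
  ii <- apply(apply(m, 2L, cumsum), 1L, cumsum)
  ii <- t(ii)
  rbind(0, cbind(0, ii))
}

# Rectangle sums centered on every pixel: entry (r, c) is the sum over
# rows r+a0..r+a1, cols c+b0..c+b1 (indices clamped; callers mask the
# border region where the filter does not fit).
boxAll <- function(ii, a0, a1, b0, b1, H, W) {
  cl <- function(x, n) pmin(pmax(x, 1L), n)
  r0 <- cl(seq_len(H) + a0, H + 1L); r1 <- cl(seq_len(H) + a1 + 1L, H + 1L)
  c0 <- cl(seq_len(W) + b0, W + 1L); c1 <- cl(seq_len(W) + b1 + 1L, W + 1L)
  ii[r1, c1] - ii[r0, c1] - ii[r1, c0] + ii[r0, c0]
}

# Box-filter det-Hessian responses at one filter size L (odd, multiple of 3).
surfResponse <- function(ii, L, H, W) {
  l <- L %/% 3L
  b <- (L - 1L) %/% 2L
  h <- l %/% 2L
  dxx <- boxAll(ii, -l + 1L, l - 1L, -b, b, H, W) -
    3 * boxAll(ii, -l + 1L, l - 1L, -h, -h + l - 1L, H, W)
  dyy <- boxAll(ii, -b, b, -l + 1L, l - 1L, H, W) -
    3 * boxAll(ii, -h, -h + l - 1L, -l + 1L, l - 1L, H, W)
  dxy <- boxAll(ii, -l, -1L, 1L, l, H, W) +
    boxAll(ii, 1L, l, -l, -1L, H, W) -
    boxAll(ii, -l, -1L, -l, -1L, H, W) -
    boxAll(ii, 1L, l, 1L, l, H, W)
  inv <- 1 / (L * L)
  det <- (dxx * inv) * (dyy * inv) - (0.9 * dxy * inv)^2
  valid <- matrix(FALSE, H, W)
  if (H - b >= b + 1L && W - b >= b + 1L)
    valid[(b + 1L):(H - b), (b + 1L):(W - b)] <- TRUE
  det[!valid] <- -Inf
  det
}

local3Max <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0L || dc != 0L) out <- pmax(out, shiftPad(m, dr, dc))
  out
}

#' SURF interest points by det-Hessian box filters
#'
#' Approximates \eqn{\det H = L_{xx} L_{yy} - (0.9 L_{xy})^2} with box
#' filters of sizes 9, 15, 21, 27 px on the integral image, then keeps
#' local maxima over a 3 x 3 x scale neighborhood above \code{threshold}
#' (at the outer scales the scale comparison is one-sided). The keypoint
#' scale is the usual \eqn{\sigma = 1.2 L / 9}.
#'
#' @param image gray matrix, at least 16 x 16.
#' @param threshold det-Hessian acceptance threshold.
#' @param maxKeypoints cap on returned keypoints (strongest first).
#' @return data.frame with columns \code{row, col, scale, detH} (possibly
#'   zero rows).
#' @export
surfKeypoints <- function(image, threshold = 1e-4, maxKeypoints = 200L) {
  H <- nrow(image); W <- ncol(image)
  if (H < 16L || W < 16L) stop("image must be at least 16x16")
  ii <- integralImage(image)
  sizes <- c(9L, 15L, 21L, 27L)
  resp <- lapply(sizes, surfResponse, ii = ii, H = H, W = W)
  kp <- list()
  for (s in seq_along(sizes)) {
    m <- resp[[s]]
    peak <- m >= local3Max(m) & is.finite(m) & m > threshold
    neigh <- if (s > 1L) pmax(local3Max(resp[[s - 1L]]), -Inf) else NULL
    if (!is.null(neigh)) peak <- peak & (m >= neigh)
    if (s < length(sizes)) peak <- peak & (m >= local3Max(resp[[s + 1L]]))
    w <- which(peak, arr.ind = TRUE)
    if (nrow(w))
      kp[[s]] <- data.frame(row = w[, 1L], col = w[, 2L],
                            scale = 1.2 * sizes[s] / 9,
                            detH = m[w])
  }
  out <- if (length(kp)) do.call(rbind, kp)
         else data.frame(row = integer(), col = integer(),
                         scale = numeric(), detH = numeric())
  out <- out[order(-out$detH), , drop = FALSE]
  rownames(out) <- NULL
  head(out, maxKeypoints)
}

# Haar-wavelet response sums around one keypoint: samples on a grid of
# spacing sigma inside a window of side 20*sigma; each response is a box
# difference of size ~2*sigma. Returns c(sum dx, sum dy, sum |dx|, sum |dy|).
haarSums <- function(ii, H, W, row, col, sigma) {
  s <- max(1L, round(sigma))
  grid <- seq(-9.5, 9.5, by = 1) * sigma
  rr <- round(row + grid); cc <- round(col + grid)
  ok_r <- rr - s >= 1L & rr + s <= H
  ok_c <- cc - s >= 1L & cc + s <= W
  rr <- rr[ok_r]; cc <- cc[ok_c]
  if (!length(rr) || !length(cc)) return(numeric(4L))
  pts <- expand.grid(r = rr, c = cc)
  rect <- function(r0, r1, c0, c1)
    ii[cbind(r1 + 1L, c1 + 1L)] - ii[cbind(r0, c1 + 1L)] -
      ii[cbind(r1 + 1L, c0)] + ii[cbind(r0, c0)]
  # equal-size half-boxes (2s rows x s cols and s rows x 2s cols)
  dx <- rect(pts$r - s + 1L, pts$r + s, pts$c + 1L, pts$c + s) -
    rect(pts$r - s + 1L, pts$r + s, pts$c - s, pts$c - 1L)
  dy <- rect(pts$r + 1L, pts$r + s, pts$c - s + 1L, pts$c + s) -
    rect(pts$r - s, pts$r - 1L, pts$c - s + 1L, pts$c + s)
  c(sum(dx), sum(dy), sum(abs(dx)), sum(abs(dy)))
}

#' Fixed 13-slot SURF summary vector
#'
#' Aggregates a variable-length keypoint set into a fixed-length
#' descriptor: \code{[count; mean, sd, max of det-Hessian responses; mean
#' of (sum dx, sum dy, sum |dx|, sum |dy|) of the Haar responses over each
#' keypoint's neighborhood; sd of the same four; mean keypoint scale]}.
#' With no keypoints all 13 slots are zero. The layout is this package's
#' own fixed construction.
#'
#' @param image gray matrix.
#' @param keypoints output of [surfKeypoints]; computed if missing.
#' @return numeric vector of length 13.
#' @export
surfSummary <- function(image, keypoints = NULL) {
  if (is.null(keypoints)) keypoints <- surfKeypoints(image)
  if (nrow(keypoints) == 0L) return(numeric(13L))
  ii <- integralImage(image)
  H <- nrow(image); W <- ncol(image)
  hm <- t(vapply(seq_len(nrow(keypoints)), function(i)
    haarSums(ii, H, W, keypoints$row[i], keypoints$col[i],
             keypoints$scale[i]), numeric(4L)))
  sd0 <- function(x) if (length(x) > 1L) sd(x) else 0
  c(nrow(keypoints),
    mean(keypoints$detH), sd0(keypoints$detH), max(keypoints$detH),
    colMeans(hm),
    apply(hm, 2L, sd0),
    mean(keypoints$scale))
}

#' Fuse HOG, SURF and LBP into the hybrid feature vector
#'
#' Lossless concatenation in the order (HOG, SURF, LBP) with a span
#' manifest; component lengths are checked against the fixed layout
#' 3780 + 13 + 59 = 3852.
#'
#' @param hog length-3780 HOG descriptor.
#' @param surf length-13 SURF summary.
#' @param lbp length-59 LBP histogram.
#' @return a [FeatureVector-class] of length 3852 with spans \code{hog},
#'   \code{surf}, \code{lbp}.
#' @export
fuseHFE <- function(hog, surf, lbp) {
  if (length(hog) != 3780L) stop("hog component must have length 3780")
  if (length(surf) != 13L) stop("surf component must have length 13")
  if (length(lbp) != 59L) stop("lbp component must have length 59")
  new("FeatureVector",
      values = c(as.numeric(hog), as.numeric(surf), as.numeric(lbp)),
      spans = list(hog = c(0L, 3780L), surf = c(3780L, 3793L),
                   lbp = c(3793L, 3852L)))
}

#' Hybrid features of one lesion patch
#'
#' Convenience wrapper: HOG on the patch resized to the 128 x 64 window,
#' LBP and SURF on the patch resized to 64 x 64, fused with [fuseHFE].
#'
#' @param patch gray matrix (MADF-filtered, FBB-cropped lesion patch).
#' @return a [FeatureVector-class] of length 3852.
#' @export
hfeFeatures <- function(patch) {
  assertGray(patch, range01 = FALSE)
  sq <- clip01(resizeGray(patch, 64L, 64L))
  fuseHFE(hogDescriptor(patch), surfSummary(sq), lbpHistogram(sq))
}
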