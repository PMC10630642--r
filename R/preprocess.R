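# Input standardization: ROI truncation, RGB -> gray, and the augmentation
# set (translate, resize, slice_crop, magnify, rotate, flip, brightness).

.AUG_OPS <- c("translate", "resize", "slice_crop", "magnify", "rotate",
              "flip", "brightness")

#' Convert an RGB array to a grayscale matrix
#'
#' Luma conversion with ITU-R BT.601 weights,
#' \eqn{Y = 0.299 R + 0.587 G + 0.114 B}, rescaled to \code{[0, 1]}
#' (integer-coded inputs are divided by 255).
#'
#' @param rgb \code{height x width x 3} numeric array, 8-bit
#'   (\code{0..255}) or float (\code{[0, 1]}).
#' @return numeric matrix in \code{[0, 1]}.
#' @export
toGray <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("expected a height x width x 3 RGB array")
  y <- 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
  if (max(rgb) > 1) y <- y / 255
  y <- clip01(y)
  if (!is.matrix(y)) y <- matrix(y, dim(rgb)[1L], dim(rgb)[2L])
  y
}

#' Crop a fixed-margin region of interest
#'
#' Strips a uniform border band (corner annotations, vignetting) of
#' \code{marginFraction} of each dimension per side; the output has
#' \code{ceiling(dim * (1 - 2 * margin))} pixels per axis.
#'
#' @param image gray matrix.
#' @param marginFraction per-side margin in \code{[0, 0.45]}.
#' @return cropped gray matrix; at least 32 x 32 or an error.
#' @export
cropROI <- function(image, marginFraction = 0.1) {
  assertGray(image, range01 = FALSE)
  if (marginFraction < 0 || marginFraction > 0.45)
    stop("marginFraction must be in [0, 0.45]")
  keep <- ceiling(dim(image) * (1 - 2 * marginFraction))
  if (any(keep < 32L))
    stop("ROI crop would leave less than 32x32 pixels")
  r0 <- floor((nrow(image) - keep[1L]) / 2)
  c0 <- floor((ncol(image) - keep[2L]) / 2)
  image[(r0 + 1L):(r0 + keep[1L]), (c0 + 1L):(c0 + keep[2L]), drop = FALSE]
}

#' Augmentation specification
#'
#' @param ops character vector of op instances, each one of
#'   \code{translate, resize, slice_crop, magnify, rotate, flip,
#'   brightness}; an op may repeat.
#' @param params named list of per-op parameter ranges; recognized entries
#'   (with defaults): \code{translate} max shift fraction 0.1;
#'   \code{resize} scale range c(0.8, 1.2); \code{slice_crop} crop
#'   fraction 0.8; \code{magnify} zoom range c(1.1, 1.5); \code{rotate}
#'   degree range c(-30, 30); \code{flip} axis "h", "v" or "random";
#'   \code{brightness} delta range c(-0.15, 0.15).
#' @param seed integer seed for the parameter draws.
#' @return an \code{augmentSpec} list.
#' @export
augmentSpec <- function(ops = c("flip", "rotate", "brightness"),
                        params = list(), seed = 1L) {
  bad <- setdiff(ops, .AUG_OPS)
  if (length(bad))
    stop("unknown augmentation op(s): ", paste(bad, collapse = ", "))
  defaults <- list(translate = 0.1, resize = c(0.8, 1.2), slice_crop = 0.8,
                   magnify = c(1.1, 1.5), rotate = c(-30, 30), flip = "random",
                   brightness = c(-0.15, 0.15))
  defaults[names(params)] <- params
  structure(list(ops = ops, params = defaults, seed = as.integer(seed)),
            class = "augmentSpec")
}

applyAug <- function(image, op, p) {
  nr <- nrow(image); nc <- ncol(image)
  out <- switch(op,
    translate = {
      s <- p$translate
      dr <- round(runif(1, -s, s) * nr); dc <- round(runif(1, -s, s) * nc)
      shiftPad(image, dr, dc)
    },
    resize = {
      f <- runif(1, p$resize[1L], p$resize[2L])
      resizeGray(image, max(8L, round(nr * f)), max(8L, round(nc * f)))
    },
    slice_crop = {
      f <- p$slice_crop
      kr <- max(8L, round(nr * f)); kc <- max(8L, round(nc * f))
      r0 <- sample.int(nr - kr + 1L, 1L); c0 <- sample.int(nc - kc + 1L, 1L)
      image[r0:(r0 + kr - 1L), c0:(c0 + kc - 1L), drop = FALSE]
    },
    magnify = {
      z <- runif(1, p$magnify[1L], p$magnify[2L])
      kr <- max(8L, round(nr / z)); kc <- max(8L, round(nc / z))
      r0 <- floor((nr - kr) / 2) + 1L; c0 <- floor((nc - kc) / 2) + 1L
      image[r0:(r0 + kr - 1L), c0:(c0 + kc - 1L), drop = FALSE]
    },
    rotate = {
      a <- runif(1, p$rotate[1L], p$rotate[2L])
      if (a == 0) image else rotateGray(image, a)
    },
    flip = {
      ax <- p$flip
      if (identical(ax, "random")) ax <- sample(c("h", "v"), 1L)
      if (ax == "h") image[, rev(seq_len(nc)), drop = FALSE]
      else image[rev(seq_len(nr)), , drop = FALSE]
    },
    brightness = {
      d <- if (length(p$brightness) == 2L)
        runif(1, p$brightness[1L], p$brightness[2L]) else p$brightness
      image + d
    })
  if (!all(dim(out) == c(nr, nc))) out <- resizeGray(out, nr, nc)
  clip01(out)
}

# Rotation about the center with replicated-edge sampling.
rotateGray <- function(image, degrees) {
  nr <- nrow(image); nc <- ncol(image)
  th <- degrees * pi / 180
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  rr <- matrix(seq_len(nr), nr, nc) - cr
  cv <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  sr <- pmin(pmax(round(cr + cos(th) * rr - sin(th) * cv), 1L), nr)
  sc <- pmin(pmax(round(cc + sin(th) * rr + cos(th) * cv), 1L), nc)
  matrix(image[cbind(as.vector(sr), as.vector(sc))], nr, nc)
}

#' Apply an augmentation specification
#'
#' Produces one output image per op instance in \code{spec$ops}; random
#' parameters are drawn under the spec seed, and every output is resized
#' back to the input shape and clipped to \code{[0, 1]}.
#'
#' @param image gray matrix in \code{[0, 1]}.
#' @param spec an [augmentSpec]; an empty op list yields an empty list.
#' @return list of gray matrices, one per op instance.
#' @export
augmentImage <- function(image, spec) {
  assertGray(image)
  stopifnot(inherits(spec, "augmentSpec"))
  if (length(spec$ops) == 0L) return(list())
  withSeed(spec$seed,
           lapply(spec$ops, function(op) applyAug(image, op, spec$params)))
}
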