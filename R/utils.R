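# Internal helpers shared across modules.

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Validate a grayscale image: numeric matrix, finite, in [0,1].
assertGray <- function(img, arg = "image", range01 = TRUE) {
  if (!is.matrix(img) || !is.numeric(img))
    stop(arg, " must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(img)))
    stop(arg, " contains non-finite pixels", call. = FALSE)
  if (range01 && (min(img) < 0 || max(img) > 1))
    stop(arg, " must have values in [0, 1]", call. = FALSE)
  invisible(img)
}

# Shift a matrix by (dr, dc) with replicated (Neumann) borders.
shiftPad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Bilinear resize keeping the (row, col) convention; EBImage's first
# dimension maps onto rows here, so w/h follow nrow/ncol.
resizeGray <- function(img, nr, nc) {
  out <- EBImage::resize(img, w = nr, h = nc)
  matrix(as.numeric(out), nr, nc)
}

grayTo224 <- function(img) {
  m <- clip01(resizeGray(img, 224L, 224L))
  array(rep(m, 3L), dim = c(224L, 224L, 3L))
}

# Derive a per-stage seed from the pipeline's global seed; stays < 2^31.
deriveSeed <- function(seed, stage) {
  ((as.numeric(seed) %% 32768) * 65521 + stage * 7919) %% 2147483647
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Read an image file as a grayscale matrix
#'
#' Reads PNG/JPEG/TIFF via EBImage. Multi-channel images are converted with
#' [toGray]; single-channel data is rescaled to \code{[0, 1]} if stored as
#' 8-bit.
#'
#' @param path image file.
#' @return numeric matrix in \code{[0, 1]}, \code{[row, col]} indexed.
#' @export
readGrayImage <- function(path) {
  im <- EBImage::readImage(path)
  a <- as.array(im)
  # EBImage stores (x, y[, c]); transpose to (row, col)
  if (length(dim(a)) == 2L) {
    m <- t(a)
  } else if (dim(a)[3L] >= 3L) {
    rgb <- aperm(a[, , 1:3], c(2L, 1L, 3L))
    return(toGray(rgb))
  } else {
    m <- t(a[, , 1L])
  }
  if (max(m) > 1) m <- m / 255
  clip01(m)
}

#' Write a grayscale matrix as an 8-bit PNG
#'
#' @param img numeric matrix in \code{[0, 1]}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGrayImage <- function(img, path) {
  assertGray(img)
  EBImage::writeImage(t(img), path, type = "png", bits.per.sample = 8L)
  invisible(path)
}
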