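# Synthetic dermoscopy scenes: lighter skin background, darker elliptical
# lesion with an irregular (radial-Fourier) border, optional within-lesion
# texture, linear illumination gradient, multiplicative speckle, and
# optional hair polylines. Everything is seeded and bit-reproducible.

#' Lesion specification for the synthetic generator
#'
#' Describes one lesion: an ellipse whose boundary radius at polar angle
#' \eqn{\phi} is perturbed multiplicatively by a seeded random Fourier
#' series, \eqn{r(\phi) = r_0(\phi)\,(1 + b \sum_h a_h \cos(h\phi +
#' \psi_h))} with \eqn{\sum_h |a_h| = 1}, so \code{borderIrregularity}
#' \eqn{b} bounds the relative boundary excursion.
#'
#' @param center length-2 numeric, lesion center as (row, col) pixels.
#' @param radii length-2 numeric, base-ellipse radii (r_row, r_col) pixels.
#' @param borderIrregularity nonnegative amplitude of the radial
#'   perturbation; 0 gives an exact ellipse.
#' @param nHarmonics number of Fourier harmonics (>= 0).
#' @param lesionLevel,skinLevel gray levels in \code{[0, 1]};
#'   \code{lesionLevel < skinLevel} (the lesion is darker than skin).
#' @param textureAmp amplitude (relative sd) of smooth multiplicative
#'   within-lesion texture; 0 disables it.
#' @param classLabel \code{"melanoma"} or \code{"non_melanoma"}.
#' @return a \code{lesionSpec} list.
#' @export
lesionSpec <- function(center = c(64, 64), radii = c(16, 16),
                       borderIrregularity = 0, nHarmonics = 5L,
                       lesionLevel = 0.35, skinLevel = 0.8,
                       textureAmp = 0, classLabel = "non_melanoma") {
  stopifnot(length(center) == 2L, length(radii) == 2L, all(radii > 0),
            borderIrregularity >= 0, nHarmonics >= 0,
            lesionLevel >= 0, skinLevel <= 1, textureAmp >= 0)
  if (lesionLevel >= skinLevel)
    stop("lesionLevel must be below skinLevel (lesion darker than skin)")
  if (!classLabel %in% c("melanoma", "non_melanoma"))
    stop("classLabel must be 'melanoma' or 'non_melanoma'")
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 borderIrregularity = borderIrregularity,
                 nHarmonics = as.integer(nHarmonics),
                 lesionLevel = lesionLevel, skinLevel = skinLevel,
                 textureAmp = textureAmp, classLabel = classLabel),
            class = "lesionSpec")
}

#' Scene specification for the synthetic generator
#'
#' @param height,width scene size in pixels.
#' @param speckleSigma sd of the multiplicative Gaussian speckle
#'   \eqn{I = G (1 + \eta)}, \eqn{\eta \sim N(0, \sigma^2)}; 0 disables.
#' @param illuminationGradient peak-to-trough amplitude of a linear
#'   left-to-right illumination ramp added to the clean image.
#' @param hairCount number of dark hair-like polylines (0 = none).
#' @param seed integer; identical seed + specs give bit-identical output.
#' @return a \code{sceneSpec} list.
#' @export
sceneSpec <- function(height = 128L, width = 128L, speckleSigma = 0.15,
                      illuminationGradient = 0.05, hairCount = 0L,
                      seed = 1L) {
  stopifnot(height >= 16L, width >= 16L, speckleSigma >= 0, hairCount >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 speckleSigma = speckleSigma,
                 illuminationGradient = illuminationGradient,
                 hairCount = as.integer(hairCount), seed = as.integer(seed)),
            class = "sceneSpec")
}

# Seeded Fourier boundary perturbation as a function of angle phi.
boundaryPerturbation <- function(spec, scene) {
  if (spec$borderIrregularity == 0 || spec$nHarmonics == 0L)
    return(function(phi) rep(0, length(phi)))
  coef <- withSeed(deriveSeed(scene$seed, 11L), {
    a <- runif(spec$nHarmonics, 0.3, 1)
    list(a = a / sum(abs(a)), psi = runif(spec$nHarmonics, 0, 2 * pi))
  })
  b <- spec$borderIrregularity
  function(phi) {
    p <- numeric(length(phi))
    for (h in seq_len(spec$nHarmonics))
      p <- p + coef$a[h] * cos(h * phi + coef$psi[h])
    b * p
  }
}

#' Render the ground-truth lesion mask
#'
#' Rasterizes the star-convex perturbed ellipse of a [lesionSpec]. The
#' perturbation coefficients are drawn from the scene seed, so the mask is
#' bit-reproducible.
#'
#' @param spec a [lesionSpec].
#' @param scene a [sceneSpec].
#' @return logical matrix (\code{TRUE} inside the lesion).
#' @export
generateLesionMask <- function(spec, scene) {
  maxR <- spec$radii * (1 + spec$borderIrregularity)
  lo <- spec$center - maxR
  hi <- spec$center + maxR
  if (lo[1L] < 3 || lo[2L] < 3 ||
      hi[1L] > scene$height - 2 || hi[2L] > scene$width - 2)
    stop("lesion exceeds the frame: radii (with border perturbation) must ",
         "fit inside the scene with a 2-px margin")
  perturb <- boundaryPerturbation(spec, scene)
  u <- (seq_len(scene$height) - spec$center[1L]) / spec$radii[1L]
  v <- (seq_len(scene$width) - spec$center[2L]) / spec$radii[2L]
  U <- matrix(u, scene$height, scene$width)
  V <- matrix(v, scene$height, scene$width, byrow = TRUE)
  R <- sqrt(U^2 + V^2)
  phi <- atan2(U, V)
  lim <- pmax(1 + perturb(phi), 0.05)
  R <= lim
}

#' Render a clean synthetic dermoscopy image and its mask
#'
#' Paints \code{skinLevel} outside the lesion and \code{lesionLevel}
#' inside, softens the boundary with a 1-px Gaussian, applies the optional
#' within-lesion multiplicative texture and the linear illumination
#' gradient, draws hair polylines if requested, and clips to
#' \code{[0, 1]}. Speckle is \emph{not} applied here; see [addSpeckle].
#'
#' @inheritParams generateLesionMask
#' @return list with elements \code{image} (clean gray matrix) and
#'   \code{mask} (logical matrix).
#' @export
renderLesion <- function(spec, scene) {
  mask <- generateLesionMask(spec, scene)
  soft <- matrix(as.numeric(EBImage::gblur(mask * 1, sigma = 1)),
                 scene$height, scene$width)
  soft <- clip01(soft)
  g <- spec$skinLevel + (spec$lesionLevel - spec$skinLevel) * soft
  if (spec$textureAmp > 0) {
    tex <- withSeed(deriveSeed(scene$seed, 12L),
                    matrix(rnorm(scene$height * scene$width),
                           scene$height, scene$width))
    tex <- matrix(as.numeric(EBImage::gblur(tex, sigma = 1.5)),
                  scene$height, scene$width)
    tex <- tex / max(sd(tex), 1e-12) * spec$textureAmp
    g <- g * (1 + tex * soft)
  }
  if (scene$illuminationGradient != 0) {
    ramp <- (seq_len(scene$width) - 1) / max(scene$width - 1, 1L) - 0.5
    g <- g + scene$illuminationGradient *
      matrix(ramp, scene$height, scene$width, byrow = TRUE)
  }
  if (scene$hairCount > 0L) g <- drawHairs(g, scene)
  list(image = clip01(g), mask = mask)
}

# Thin dark random polylines emulating hairs.
drawHairs <- function(g, scene) {
  withSeed(deriveSeed(scene$seed, 13L), {
    for (i in seq_len(scene$hairCount)) {
      r0 <- runif(1, 1, scene$height); c0 <- runif(1, 1, scene$width)
      ang <- runif(1, 0, pi); len <- runif(1, 0.4, 0.9) * scene$width
      tseq <- seq(0, 1, length.out = ceiling(len) * 2L)
      rr <- round(r0 + tseq * len * sin(ang) +
                    3 * sin(tseq * pi * runif(1, 1, 3)))
      cc <- round(c0 + tseq * len * cos(ang))
      ok <- rr >= 1 & rr <= scene$height & cc >= 1 & cc <= scene$width
      g[cbind(rr[ok], cc[ok])] <- 0.12
    }
    g
  })
}

#' Add multiplicative Gaussian speckle
#'
#' Applies the noise model \eqn{I = \mathrm{clip}(G (1 + \eta), 0, 1)} with
#' \eqn{\eta \sim N(0, \sigma^2)} drawn i.i.d. per pixel under the given
#' seed, so \eqn{E[I] = G} away from clipping.
#'
#' @param image clean gray matrix in \code{[0, 1]}.
#' @param sigma noise sd, \code{>= 0}; 0 returns the input unchanged.
#' @param seed integer RNG seed.
#' @return speckled gray matrix in \code{[0, 1]}.
#' @export
addSpeckle <- function(image, sigma, seed = 1L) {
  assertGray(image)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single nonnegative number")
  if (sigma == 0) return(image)
  eta <- withSeed(seed, matrix(rnorm(length(image), 0, sigma),
                               nrow(image), ncol(image)))
  clip01(image * (1 + eta))
}

# Class-conditional parameter draws. Melanoma lesions have markedly more
# irregular borders, stronger and finer within-lesion texture, more
# asymmetric axes and a distinctly darker body than benign lesions — the
# contrast channels the clinical ABCD criteria describe, dosed so the
# descriptor set can resolve them under speckle.
drawLesionParams <- function(label, scene) {
  if (label == "melanoma") {
    radii <- runif(2, 13, 22)
    irr <- runif(1, 0.25, 0.45)
    tex <- runif(1, 0.10, 0.18)
    lev <- runif(1, 0.20, 0.33)
  } else {
    r1 <- runif(1, 13, 22)
    radii <- c(r1, r1 * runif(1, 0.88, 1.12))
    irr <- runif(1, 0.02, 0.10)
    tex <- runif(1, 0, 0.02)
    lev <- runif(1, 0.42, 0.55)
  }
  skin <- runif(1, 0.75, 0.88)
  maxR <- max(radii) * (1 + irr) + 4
  center <- c(runif(1, maxR, scene$height - maxR),
              runif(1, maxR, scene$width - maxR))
  lesionSpec(center = center, radii = radii, borderIrregularity = irr,
             nHarmonics = 6L, lesionLevel = lev, skinLevel = skin,
             textureAmp = tex, classLabel = label)
}

#' Generate a balanced labeled synthetic dataset
#'
#' Draws \code{nPerClass} melanoma and \code{nPerClass} non-melanoma
#' scenes. Melanoma lesions get higher border irregularity, higher
#' within-lesion texture variance and more axis asymmetry. Each record
#' holds the speckled image, the ground-truth mask, the label and the
#' lesion spec; the manifest (one row per record with every spec field) is
#' attached as \code{attr(, "manifest")}.
#'
#' @param nPerClass images per class (>= 1).
#' @param scene a [sceneSpec] giving size, speckle level and defaults.
#' @param seed integer master seed; overrides \code{scene$seed}.
#' @return list of records; each has \code{image}, \code{mask},
#'   \code{label}, \code{spec}, \code{sceneSeed}.
#' @export
makeDermoDataset <- function(nPerClass, scene = sceneSpec(), seed = scene$seed) {
  stopifnot(nPerClass >= 1L)
  labels <- rep(c("melanoma", "non_melanoma"), each = nPerClass)
  records <- vector("list", length(labels))
  manifest <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    recSeed <- as.integer(deriveSeed(seed, 100L + i))
    sc <- scene
    sc$seed <- recSeed
    spec <- withSeed(recSeed, drawLesionParams(labels[i], sc))
    clean <- renderLesion(spec, sc)
    img <- addSpeckle(clean$image, sc$speckleSigma,
                      seed = deriveSeed(recSeed, 21L))
    records[[i]] <- list(image = img, mask = clean$mask, label = labels[i],
                         spec = spec, sceneSeed = recSeed)
    manifest[[i]] <- data.frame(
      id = i, label = labels[i], seed = recSeed,
      center_row = spec$center[1L], center_col = spec$center[2L],
      r_row = spec$radii[1L], r_col = spec$radii[2L],
      border_irregularity = spec$borderIrregularity,
      n_harmonics = spec$nHarmonics, lesion_level = spec$lesionLevel,
      skin_level = spec$skinLevel, texture_amp = spec$textureAmp,
      speckle_sigma = sc$speckleSigma)
  }
  attr(records, "manifest") <- do.call(rbind, manifest)
  records
}

#' Write a synthetic dataset to disk
#'
#' Writes 8-bit PNG images and masks plus a CSV manifest
#' (\code{filename, mask, label, seed} and all lesion-spec fields).
#'
#' @param dataset output of [makeDermoDataset].
#' @param dir output directory (created if absent).
#' @return path of the manifest CSV, invisibly.
#' @export
writeDermoDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- attr(dataset, "manifest")
  manifest$filename <- sprintf("img_%04d.png", manifest$id)
  manifest$mask <- sprintf("mask_%04d.png", manifest$id)
  for (i in seq_along(dataset)) {
    writeGrayImage(dataset[[i]]$image, file.path(dir, manifest$filename[i]))
    writeGrayImage(dataset[[i]]$mask * 1, file.path(dir, manifest$mask[i]))
  }
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Canonical despeckling benchmark scene
#'
#' A fixed 96 x 96 dermoscopy-style scene — irregular-border lesion
#' filling about 60 percent of the frame, no within-lesion texture, mild
#' illumination ramp — with multiplicative speckle of the requested level.
#' Used to evaluate filters: the clean image is the metric reference.
#'
#' @param sigma speckle sd.
#' @param seed noise seed (the scene itself is fixed).
#' @return list \code{clean}, \code{noisy}, \code{mask}.
#' @export
benchmarkScene <- function(sigma = 0.2, seed = 7L) {
  scene <- sceneSpec(height = 96L, width = 96L, speckleSigma = sigma,
                     illuminationGradient = 0.05, seed = 7L)
  spec <- lesionSpec(center = c(48, 48), radii = c(29, 31),
                     borderIrregularity = 0.35, nHarmonics = 8L,
                     lesionLevel = 0.35, skinLevel = 0.8, textureAmp = 0,
                     classLabel = "melanoma")
  r <- renderLesion(spec, scene)
  list(clean = r$image, noisy = addSpeckle(r$image, sigma, seed = seed),
       mask = r$mask)
}

#' Shape and texture summaries of a labeled lesion
#'
#' Computes the mask area, the squared boundary length over area (a
#' dimensionless border-irregularity index), and the intensity variance
#' inside the lesion — the minimal statistics that separate the two
#' synthetic classes.
#'
#' @param image gray matrix.
#' @param mask logical lesion mask of the same shape.
#' @return named numeric vector \code{area}, \code{compactness}
#'   (perimeter^2 / area), \code{insideVar}.
#' @export
lesionShapeStats <- function(image, mask) {
  stopifnot(all(dim(image) == dim(mask)))
  area <- sum(mask)
  inner <- mask & shiftPad(mask, 1L, 0L) & shiftPad(mask, -1L, 0L) &
    shiftPad(mask, 0L, 1L) & shiftPad(mask, 0L, -1L)
  perim <- sum(mask & !inner)
  c(area = area,
    compactness = if (area > 0) perim^2 / area else 0,
    insideVar = if (area > 1) stats::var(image[mask]) else 0)
}
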