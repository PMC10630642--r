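# Modified anisotropic diffusion filtering (MADF). The diffusion update is
# the classical 4-neighbor Perona-Malik explicit scheme; the modification
# is the stopping rule: iterate until the multiplicative residual
# n = (I0 - F) / F looks Gaussian (excess kurtosis near 0), or until its
# correlation with the estimate stops decreasing, whichever comes first.

#' Diffusion parameters
#'
#' @param kappa edge-stopping threshold of the conductivity
#'   \eqn{c(x) = \exp(-(x/\kappa)^2)}; gradients well above \code{kappa}
#'   diffuse little (edges are preserved). Default 0.45 gray-level units,
#'   above the per-pixel speckle gradient scale at the supported noise
#'   levels (sigma up to 0.3 on bright skin) so noise diffuses while the
#'   correlation-minimum stop bounds the loss of genuine edges.
#' @param lam explicit-scheme step size in \code{(0, 0.25]}; 0.25 is the
#'   4-neighbor stability limit.
#' @param tolKurtosis Gaussianity band: the residual counts as Gaussian
#'   once its \code{|excess kurtosis|} falls to this value or below.
#'   Default 0.2, wide enough to admit the mildly platykurtic residual
#'   that clipping the multiplicative noise to \code{[0, 1]} produces,
#'   while still rejecting residuals contaminated by image structure.
#' @param patience iterations without a new minimum of \code{|rho_G|}
#'   (estimate/residual correlation) before stopping. Default 5.
#' @param maxIters hard iteration cap. Default 200.
#' @param eps division guard for the multiplicative residual.
#' @return a \code{diffusionParams} list.
#' @export
diffusionParams <- function(kappa = 0.45, lam = 0.2, tolKurtosis = 0.2,
                            patience = 5L, maxIters = 200L, eps = 1e-6) {
  stopifnot(kappa > 0, lam > 0, tolKurtosis > 0, patience >= 1L,
            maxIters >= 1L, eps > 0)
  if (lam > 0.25)
    stop("lam must be <= 0.25 (explicit 4-neighbor stability limit)")
  structure(list(kappa = kappa, lam = lam, tolKurtosis = tolKurtosis,
                 patience = as.integer(patience),
                 maxIters = as.integer(maxIters), eps = eps),
            class = "diffusionParams")
}

#' One explicit Perona-Malik diffusion step
#'
#' \eqn{F' = F + \lambda \sum_{d \in \{N,S,E,W\}} c(\nabla_d F) \nabla_d F}
#' with conductivity \eqn{c(x) = \exp(-(x/\kappa)^2)} and replicated-edge
#' (Neumann) boundaries. The scheme conserves the global mean and creates
#' no new extrema for \eqn{\lambda \le 0.25}.
#'
#' @param f gray matrix.
#' @param params a [diffusionParams].
#' @return diffused gray matrix of the same shape.
#' @export
diffusionStep <- function(f, params = diffusionParams()) {
  if (any(!is.finite(f))) stop("image contains non-finite pixels")
  acc <- 0
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    g <- shiftPad(f, d[1L], d[2L]) - f
    acc <- acc + exp(-(g / params$kappa)^2) * g
  }
  f + params$lam * acc
}

#' Multiplicative residual between a noisy image and its estimate
#'
#' \eqn{n = (I_0 - F) / \max(F, \epsilon)}: under the speckle model
#' \eqn{I_0 = G (1 + \eta)} and a perfect estimate \eqn{F = G}, the
#' residual recovers \eqn{\eta} exactly.
#'
#' @param i0 observed noisy image.
#' @param f current clean estimate, same shape.
#' @param eps positive division guard.
#' @return residual field (matrix, same shape).
#' @export
residualNoise <- function(i0, f, eps = 1e-6) {
  if (!all(dim(i0) == dim(f))) stop("i0 and f must share one shape")
  (i0 - f) / pmax(f, eps)
}

#' Excess kurtosis with biased (1/N) moment estimators
#'
#' \eqn{k = m_4 / m_2^2 - 3} with \eqn{m_j = \frac{1}{N}\sum (x-\mu)^j}.
#' Zero for a Gaussian sample in expectation; the MADF stopping signal.
#'
#' @param values numeric vector (or matrix) with at least 4 values.
#' @return excess kurtosis (scalar).
#' @export
excessKurtosis <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 4L) stop("need at least 4 values")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0) stop("zero variance: kurtosis undefined (degenerate residual)")
  mean((x - mu)^4) / m2^2 - 3
}

#' Pearson correlation of two equal-shape fields
#'
#' Flattens both fields and computes the plain Pearson correlation; used
#' for the image-intensity correlation \eqn{\rho_I = corr(I_0, F)} and the
#' noise-intensity correlation \eqn{\rho_G = corr(F, n)}.
#'
#' @param a,b numeric matrices of one shape, each with nonzero variance.
#' @return correlation in \code{[-1, 1]}.
#' @export
intensityCorrelation <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shapes must match")
  av <- as.numeric(a); bv <- as.numeric(b)
  if (sd(av) == 0 || sd(bv) == 0)
    stop("zero variance: correlation undefined")
  cor(av, bv)
}

#' Modified anisotropic diffusion filter
#'
#' Iterates [diffusionStep] from the noisy image. After every step the
#' multiplicative residual, its excess kurtosis \code{k}, the correlations
#' \code{rho_I = corr(i0, F)} and \code{rho_G = corr(F, n)} and the
#' residual mean are recorded. The loop keeps running until the extracted
#' noise has reached Gaussianity (\code{|k| <= tolKurtosis}, latched once
#' attained) \emph{and} \code{|rho_G|} has stopped attaining new minima
#' for \code{patience} iterations (the estimate and the extracted noise
#' are maximally decorrelated); both conditions must hold, and
#' \code{stopReason} names the one satisfied last (\code{"kurtosis"} or
#' \code{"correlation_min"}). \code{maxIters} is the hard cap. A
#' degenerate (zero-variance) residual counts as converged.
#'
#' @param i0 noisy gray matrix in \code{[0, 1]}.
#' @param params a [diffusionParams].
#' @return list with \code{image} (filtered matrix) and \code{diagnostics}
#'   (a [FilterDiagnostics-class]).
#' @export
madfFilter <- function(i0, params = diffusionParams()) {
  assertGray(i0)
  f <- i0
  rows <- vector("list", params$maxIters)
  reason <- "max_iters"
  bestRho <- Inf
  bestIter <- 0L
  gaussReached <- FALSE
  iter <- 0L
  while (iter < params$maxIters) {
    iter <- iter + 1L
    f <- diffusionStep(f, params)
    n <- residualNoise(i0, f, params$eps)
    degenerate <- (sd(as.numeric(n)) == 0) || (sd(as.numeric(f)) == 0)
    k <- if (degenerate) NA_real_ else excessKurtosis(n)
    rhoI <- if (degenerate) NA_real_ else intensityCorrelation(i0, f)
    rhoG <- if (degenerate) NA_real_ else intensityCorrelation(f, n)
    rows[[iter]] <- data.frame(iter = iter, k = k, rho_I = rhoI,
                               rho_G = rhoG, mean_mu = mean(n))
    if (degenerate) {
      reason <- "kurtosis"
      break
    }
    if (abs(rhoG) < bestRho) {
      bestRho <- abs(rhoG)
      bestIter <- iter
    }
    corrDone <- (iter - bestIter >= params$patience)
    gaussNow <- abs(k) <= params$tolKurtosis
    if (gaussNow && !gaussReached && corrDone) {
      reason <- "kurtosis"      # Gaussianity was the last condition to land
      break
    }
    gaussReached <- gaussReached || gaussNow
    if (gaussReached && corrDone) {
      reason <- "correlation_min"
      break
    }
  }
  diag <- new("FilterDiagnostics",
              trace = do.call(rbind, rows[seq_len(iter)]),
              stopReason = reason)
  list(image = f, diagnostics = diag)
}

#' Despeckling quality metrics: SNR, MSE, EPF
#'
#' \code{MSE = mean((ref - x)^2)};
#' \code{SNR = 10 log10(sum(ref^2) / sum((ref - x)^2))} dB (\code{Inf} for
#' a perfect result); \code{EPF} is the Pearson correlation of the
#' mean-removed 4-neighbor Laplacians of reference and result — 1 when all
#' edge detail is preserved. Higher SNR and EPF mean better noise removal
#' and edge preservation.
#'
#' @param reference clean ground-truth gray matrix.
#' @param filtered filtered gray matrix.
#' @param noisy optional unfiltered noisy image; when given, its metrics
#'   are reported alongside for comparison.
#' @return data.frame with columns \code{which, snr_db, mse, epf}.
#' @export
qualityMetrics <- function(reference, filtered, noisy = NULL) {
  one <- function(x, label) {
    if (!all(dim(reference) == dim(x))) stop("shapes must match")
    err <- sum((reference - x)^2)
    mse <- mean((reference - x)^2)
    snr <- if (err == 0) Inf else 10 * log10(sum(reference^2) / err)
    lr <- laplacian4(reference); lx <- laplacian4(x)
    lr <- lr - mean(lr); lx <- lx - mean(lx)
    if (sd(as.numeric(lr)) == 0 || sd(as.numeric(lx)) == 0)
      stop("EPF undefined for flat images")
    data.frame(which = label, snr_db = snr, mse = mse,
               epf = cor(as.numeric(lr), as.numeric(lx)))
  }
  out <- one(filtered, "filtered")
  if (!is.null(noisy)) out <- rbind(out, one(noisy, "noisy"))
  out
}

# 4-neighbor Laplacian with replicated borders.
laplacian4 <- function(m) {
  shiftPad(m, -1L, 0L) + shiftPad(m, 1L, 0L) +
    shiftPad(m, 0L, -1L) + shiftPad(m, 0L, 1L) - 4 * m
}
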