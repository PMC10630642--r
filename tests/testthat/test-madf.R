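test_that("diffusion step is conservative and extremum-bounded", {
  f <- wavyImage()
  expect_identical(diffusionStep(matrix(0.4, 16, 16)), matrix(0.4, 16, 16))
  for (seed in 1:3) {
    g <- withr::with_seed(seed, matrix(runif(64 * 64), 64, 64))
    g2 <- diffusionStep(g)
    expect_lt(abs(mean(g2) - mean(g)), 1e-12)
    expect_gte(min(g2), min(g) - 1e-12)
    expect_lte(max(g2), max(g) + 1e-12)
  }
  expect_error(diffusionStep(matrix(c(NA, 1, 2, 3), 2, 2)), "non-finite")
})

test_that("an isolated impulse is strictly damped", {
  f <- matrix(0.2, 21, 21)
  f[11, 11] <- 0.9
  f2 <- diffusionStep(f)
  expect_lt(f2[11, 11], 0.9)
  expect_gt(f2[11, 11], 0.2)
})

test_that("the multiplicative residual recovers exact ratios", {
  f <- wavyImage()
  expect_equal(residualNoise(f, f), matrix(0, 64, 64), tolerance = 1e-15)
  expect_equal(residualNoise(1.1 * f, f), matrix(0.1, 64, 64),
               tolerance = 1e-12)
  z <- matrix(0, 4, 4)
  expect_true(all(is.finite(residualNoise(matrix(1, 4, 4), z, eps = 1e-6))))
  expect_error(residualNoise(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("excess kurtosis matches an independent estimator", {
  expect_equal(excessKurtosis(rep(c(-1, 1), 50)), -2, tolerance = 1e-12)
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rexp(500)^1.5 - rnorm(500))
    expect_equal(excessKurtosis(x),
                 unname(e1071::kurtosis(x, type = 1)),
                 tolerance = 1e-12)
  }
  expect_error(excessKurtosis(rep(1, 100)), "variance")
  expect_error(excessKurtosis(c(1, 2, 3)), "at least 4")
})

test_that("kurtosis calibration: Gaussian near 0, Laplace near 3", {
  g <- withr::with_seed(1, rnorm(1e5))
  expect_lt(abs(excessKurtosis(g)), 0.05)
  lap <- withr::with_seed(2, rexp(1e5) - rexp(1e5))
  expect_lt(abs(excessKurtosis(lap) - 3), 0.2)
})

test_that("intensity correlation is plain Pearson with guards", {
  a <- wavyImage()
  expect_equal(intensityCorrelation(a, a), 1)
  expect_equal(intensityCorrelation(a, -a), -1)
  n1 <- withr::with_seed(3, matrix(rnorm(256^2), 256, 256))
  n2 <- withr::with_seed(4, matrix(rnorm(256^2), 256, 256))
  expect_lt(abs(intensityCorrelation(n1, n2)), 0.02)
  expect_error(intensityCorrelation(a, matrix(1, 64, 64)), "variance")
})

test_that("the filter converges immediately on a speckle-free image", {
  res <- madfFilter(matrix(0.6, 32, 32))
  expect_equal(nrow(filterTrace(res$diagnostics)), 1L)
  expect_equal(stopReason(res$diagnostics), "kurtosis")
})

test_that("the stopping rule fires before the iteration cap on speckle", {
  b <- benchmarkScene(sigma = 0.2, seed = 7L)
  res <- madfFilter(b$noisy, diffusionParams(maxIters = 200L))
  tr <- filterTrace(res$diagnostics)
  expect_lt(nrow(tr), 200L)
  expect_true(stopReason(res$diagnostics) %in%
                c("kurtosis", "correlation_min"))
  expect_equal(nrow(tr), max(tr$iter))
  if (stopReason(res$diagnostics) == "kurtosis")
    expect_lte(abs(tr$k[nrow(tr)]), diffusionParams()$tolKurtosis)
})

test_that("quality metrics agree with closed forms", {
  ref <- wavyImage()
  qm <- qualityMetrics(ref, ref)
  expect_equal(qm$mse, 0)
  expect_equal(qm$epf, 1)
  expect_true(is.infinite(qm$snr_db))
  qm2 <- qualityMetrics(ref, ref + 0.1)
  expect_equal(qm2$mse, 0.01, tolerance = 1e-12)
  expect_equal(qm2$epf, 1, tolerance = 1e-12)  # Laplacian kills constants
  expect_error(qualityMetrics(matrix(0.5, 8, 8), matrix(0.4, 8, 8)), "flat")
})

test_that("filtering improves SNR and edge correlation on speckle", {
  for (sig in c(0.1, 0.2, 0.3)) {
    b <- benchmarkScene(sigma = sig, seed = sig * 10)
    res <- madfFilter(b$noisy)
    qm <- qualityMetrics(b$clean, res$image, b$noisy)
    expect_gt(qm$snr_db[1], qm$snr_db[2])
    expect_gt(qm$epf[1], qm$epf[2])
  }
})
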