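# Independent entropy oracle: cut() + table() instead of findInterval().
entropyOracle <- function(x, nBins = 10L) {
  if (min(x) == max(x)) return(0)
  edges <- seq(min(x), max(x), length.out = nBins + 1L)
  p <- as.numeric(table(cut(x, breaks = edges, include.lowest = TRUE)))
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

test_that("full fusion concatenates HFE then CNN losslessly", {
  hfe <- runif(3852); cnn <- runif(4096)
  fv <- fuseAll(hfe, cnn)
  expect_length(featureValues(fv), 7948L)
  expect_equal(featureValues(fv)[3853], cnn[1])   # coordinate 3852, 0-based
  expect_equal(featureSpans(fv)$hfe, c(0L, 3852L))
  expect_equal(featureSpans(fv)$cnn, c(3852L, 7948L))
  expect_error(fuseAll(runif(100), cnn), "3852")
  expect_error(fuseAll(hfe, runif(5)), "4096")
  expect_true(all(featureValues(fuseAll(rep(0, 3852), rep(0, 4096))) == 0))
})

test_that("feature entropy matches analytic and oracle values", {
  expect_equal(as.numeric(featureEntropy(rep(3.7, 50))), 0)
  tenLevels <- rep(1:10, each = 5)
  expect_equal(as.numeric(featureEntropy(tenLevels, nBins = 10L)),
               log2(10), tolerance = 1e-12)
  for (seed in 1:10) {
    x <- withr::with_seed(seed, rnorm(200)^3)
    expect_equal(as.numeric(featureEntropy(x)), entropyOracle(x),
                 tolerance = 1e-12)
  }
  expect_error(featureEntropy(1), "2 samples")
})

test_that("the selector keeps the k highest-entropy columns", {
  m <- withr::with_seed(1, cbind(matrix(rnorm(50 * 5), 50, 5),
                                 matrix(2, 50, 20)))
  sel <- fitEntropySelector(m, k = 5L, nBins = 8L)
  expect_identical(selectedIndices(sel), 1:5)   # constants are excluded
  expect_error(fitEntropySelector(m, k = 30L), "exceeds")
  perm <- withr::with_seed(2, sample(50))
  sel2 <- fitEntropySelector(m[perm, ], k = 5L, nBins = 8L)
  expect_identical(selectedIndices(sel2), selectedIndices(sel))
})

test_that("ties break deterministically toward lower column indices", {
  x <- withr::with_seed(3, rnorm(40))
  m <- cbind(x, x, x, x)                        # identical entropies
  colnames(m) <- NULL
  sel <- fitEntropySelector(m, k = 2L)
  expect_identical(selectedIndices(sel), 1:2)
})

test_that("selection is an exact column subset, reused at test time", {
  m <- withr::with_seed(4, matrix(rnorm(30 * 12), 30, 12))
  sel <- fitEntropySelector(m, k = 6L)
  sub <- applySelector(sel, m)
  expect_equal(ncol(sub), 6L)
  for (j in seq_len(6L))
    expect_identical(sub[, j], m[, selectedIndices(sel)[j]])
  # refitting on the selected subset with the same k is idempotent
  sel2 <- fitEntropySelector(sub, k = 6L)
  expect_identical(selectedIndices(sel2), 1:6)
  expect_error(applySelector(sel, m[, 1:5]), "dimension mismatch")
})

test_that("entropy scores are invariant to affine column rescaling", {
  m <- withr::with_seed(5, matrix(rexp(40 * 6), 40, 6))
  s1 <- entropyScores(fitEntropySelector(m, k = 3L))
  s2 <- entropyScores(fitEntropySelector(m * 7 - 2, k = 3L))
  expect_equal(s1, s2, tolerance = 1e-9)
})
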