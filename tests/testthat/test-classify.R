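# Toy problem: two linearly separable clusters embedded in 1280-d.
separableToy <- function(n = 40L, seed = 1L) {
  withr::with_seed(seed, {
    y <- rep(c("melanoma", "non_melanoma"), each = n / 2)
    x <- matrix(rnorm(n * 1280, sd = 0.02), n, 1280)
    x[, 1] <- x[, 1] + ifelse(y == "melanoma", 1, -1)
    list(x = x, y = y)
  })
}

test_that("the default head separates a linearly separable toy", {
  toy <- separableToy()
  m <- trainHead(toy$x, toy$y, seed = 1L)
  expect_equal(as.character(predictHead(m, toy$x)), toy$y)
  m2 <- trainHead(toy$x, toy$y, seed = 1L)
  expect_identical(predictHead(m2, toy$x), predictHead(m, toy$x))
  expect_error(trainHead(toy$x, rep("melanoma", nrow(toy$x))),
               "both classes")
  expect_error(trainHead(toy$x[1:5, ], toy$y[1:5]), "at least 10")
  expect_error(trainHead(toy$x, rep(c("a", "b"), 20)), "melanoma")
})

test_that("alternative heads train and predict on the toy", {
  # lower-dimensional embedding: distance-based heads (knn) are not
  # expected to survive 1280 standardized noise dimensions
  toy <- withr::with_seed(1, {
    y <- rep(c("melanoma", "non_melanoma"), each = 20)
    x <- matrix(rnorm(40 * 64, sd = 0.1), 40, 64)
    x[, 1:32] <- x[, 1:32] + ifelse(y == "melanoma", 1, -1)
    list(x = x, y = y)
  })
  for (ht in c("dt", "rf", "knn", "svm")) {
    m <- trainHead(toy$x, toy$y, spec = headSpec(ht), seed = 2L)
    acc <- mean(as.character(predictHead(m, toy$x)) == toy$y)
    expect_gt(acc, 0.9)
  }
})

test_that("confusion counts follow the melanoma-positive convention", {
  y <- c("melanoma", "melanoma", "non_melanoma", "non_melanoma")
  cm <- confusionCounts(y, y)
  expect_equal(unname(counts(cm)), c(2, 0, 0, 2))
  flipped <- rev(y)
  cmf <- confusionCounts(flipped, y)
  expect_equal(counts(cmf)[["TP"]], 0)
  expect_equal(counts(cmf)[["TN"]], 0)
  expect_equal(sum(counts(cmf)), 4)
  expect_error(confusionCounts(c("x", "y"), y[1:2]), "melanoma")
})

test_that("metric formulas reproduce hand-computed ratios", {
  allGood <- confusionFromCounts(1, 0, 0, 1)
  expect_equal(unname(classMetrics(allGood)), rep(1, 4))
  cm <- confusionFromCounts(11076, 120, 94, 4880)
  m <- classMetrics(cm)
  expect_equal(m[["accuracy"]], 15956 / 16170, tolerance = 1e-12)
  expect_equal(m[["sensitivity"]], 11076 / 11196, tolerance = 1e-12)
  expect_equal(m[["specificity"]], 4880 / 4974, tolerance = 1e-12)
  expect_equal(m[["precision"]], 11076 / 11170, tolerance = 1e-12)
  m10 <- classMetrics(confusionFromCounts(110760, 1200, 940, 48800))
  expect_equal(m, m10, tolerance = 1e-12)     # ratio invariance
  expect_error(classMetrics(confusionFromCounts(0, 0, 0, 0)), "empty")
  noNeg <- classMetrics(confusionFromCounts(3, 1, 0, 0))
  expect_true(is.na(noNeg[["specificity"]]))  # undefined, not fabricated
})

test_that("stratified folds partition every sample exactly once", {
  y <- rep(c("melanoma", "non_melanoma"), c(60, 40))
  f <- stratifiedFolds(y, k = 5L, seed = 1L)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f, y) >= 8))
  expect_identical(f, stratifiedFolds(y, k = 5L, seed = 1L))
  expect_error(stratifiedFolds(y[1:3], k = 5L), "at least k")
})

test_that("cross-validation is leak-free and self-consistent", {
  toy <- separableToy(n = 60L, seed = 3L)
  cv <- kfoldCV(toy$x, toy$y, k = 5L, seed = 1L, kSelect = 100L)
  expect_equal(nrow(cv$perFold), 5L)
  expect_equal(unname(cv$mean["accuracy"]),
               mean(cv$perFold$accuracy), tolerance = 1e-12)
  expect_equal(sum(counts(cv$confusion)), 60)
  cv2 <- kfoldCV(toy$x, toy$y, k = 5L, seed = 1L, kSelect = 100L)
  expect_identical(cv$perFold, cv2$perFold)
  # perturbing fold 1's held-out rows must not change fold 1's selector
  x3 <- toy$x
  test1 <- cv$folds == 1L
  x3[test1, ] <- withr::with_seed(9, matrix(rnorm(sum(test1) * 1280),
                                            sum(test1), 1280))
  cv3 <- kfoldCV(x3, toy$y, k = 5L, seed = 1L, kSelect = 100L)
  expect_identical(cv3$selectorChecksums[1], cv$selectorChecksums[1])
  expect_error(kfoldCV(toy$x[1:3, ], toy$y[1:3], k = 5L), "at least k")
})

test_that("the stratified split honors the 70/30 default", {
  y <- rep(c("melanoma", "non_melanoma"), each = 50)
  tr <- trainTestSplit(y, seed = 2L)
  expect_equal(sum(tr[y == "melanoma"]), 35)
  expect_equal(sum(tr[y == "non_melanoma"]), 35)
})
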