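# Brute-force O(n^2) oracle: shortest interval with mass >= tau * total.
bruteInterval <- function(mass, tau) {
  total <- sum(mass)
  best <- NULL
  bestLen <- length(mass) + 1L
  for (s in seq_along(mass)) {
    for (e in s:length(mass)) {
      if (sum(mass[s:e]) >= tau * total) {
        if ((e - s + 1L) < bestLen) {
          bestLen <- e - s + 1L
          best <- c(s - 1L, e)
        }
        break  # longer e only lengthens the interval
      }
    }
  }
  as.integer(best)
}

test_that("darkness map keeps only below-median mass", {
  expect_identical(darknessMap(matrix(0.5, 8, 8)), matrix(0, 8, 8))
  m <- matrix(0.6, 9, 9)
  m[5, 5] <- 0.3
  d <- darknessMap(m)
  expect_equal(sum(d > 0), 1L)
  expect_equal(d[5, 5], 0.3, tolerance = 1e-12)
  img <- wavyImage()
  expect_equal(sum(darknessMap(img)),
               sum((median(img) - img)[img < median(img)]),
               tolerance = 1e-12)
})

test_that("axis profiles conserve total mass", {
  d <- matrix(0, 10, 12)
  expect_true(all(axisProfile(d, "row")$mass == 0))
  d[3, 7] <- 2.5
  pr <- axisProfile(d, "row"); pc <- axisProfile(d, "col")
  expect_equal(which(pr$mass > 0), 3L)
  expect_equal(which(pc$mass > 0), 7L)
  d2 <- matrix(runif(120), 10, 12)
  expect_equal(sum(axisProfile(d2, "row")$mass), sum(d2), tolerance = 1e-12)
  expect_equal(axisProfile(d2, "col")$prefix[12], sum(d2), tolerance = 1e-12)
})

test_that("smallest mass interval matches analytic cases", {
  oneHot <- c(rep(0, 5), 3, rep(0, 4))
  expect_equal(smallestMassInterval(list(mass = oneHot,
                                         prefix = cumsum(oneHot)), 0.95),
               c(5L, 6L))
  unif <- rep(1, 100)
  expect_equal(smallestMassInterval(list(mass = unif, prefix = cumsum(unif)),
                                    0.5),
               c(0L, 50L))
  expect_error(smallestMassInterval(list(mass = rep(0, 5),
                                         prefix = rep(0, 5)), 0.9),
               "zero total mass")
})

test_that("two-pointer search equals the exhaustive oracle", {
  for (case in 1:200) {
    mass <- withr::with_seed(case, {
      n <- sample(5:40, 1)
      round(runif(n)^2 * 10, 3)
    })
    if (sum(mass) == 0) mass[1] <- 1
    tau <- withr::with_seed(1000 + case, runif(1, 0.3, 1))
    p <- list(mass = mass, prefix = cumsum(mass))
    expect_identical(smallestMassInterval(p, tau), bruteInterval(mass, tau))
  }
})

test_that("shrinking tau never enlarges the interval", {
  mass <- withr::with_seed(9, runif(60)^2)
  p <- list(mass = mass, prefix = cumsum(mass))
  lens <- vapply(c(0.95, 0.8, 0.6, 0.4, 0.2), function(tau) {
    iv <- smallestMassInterval(p, tau); iv[2] - iv[1]
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("FBB brackets a clean synthetic lesion", {
  cs <- circleScene(radius = 10)
  box <- fbbDetect(cs$image)
  cc <- boxCoords(box)
  expect_true(cc["rowStart"] <= 63 && cc["rowStop"] > 63)
  expect_true(cc["colStart"] <= 63 && cc["colStop"] > 63)
  expect_gte(boxIoU(box, maskBBox(cs$mask)), 0.6)
  expect_error(fbbDetect(matrix(0.5, 32, 32)), "no lesion detected")
})

test_that("box cropping pads and clamps to the frame", {
  img <- wavyImage(30, 30)
  box <- new("BoundingBox", rowStart = 0L, rowStop = 5L,
             colStart = 26L, colStop = 30L)
  patch <- cropBox(img, box, pad = 2L)
  expect_equal(dim(patch), c(7L, 6L))
  expect_equal(boxIoU(box, box), 1)
  far <- new("BoundingBox", rowStart = 20L, rowStop = 25L,
             colStart = 0L, colStop = 4L)
  expect_equal(boxIoU(box, far), 0)
})
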