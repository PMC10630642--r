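test_that("gradients implement the [-1,0,1] kernel and polar forms", {
  img <- matrix(0, 5, 5)
  img[3, 4] <- 10; img[3, 2] <- 4      # horizontal neighbors of (3,3)
  g <- imageGradients(img)
  expect_equal(g$gx[3, 3], 6)
  img2 <- matrix(0, 5, 5)
  img2[4, 3] <- 4; img2[2, 3] <- 1     # vertical neighbors
  g2 <- imageGradients(img2)
  expect_equal(g2$gy[3, 3], 3)
  gm <- list(gx = 3, gy = 4)
  expect_equal(sqrt(gm$gx^2 + gm$gy^2), 5)  # magnitude form
  flat45 <- outer(1:8, 1:8, function(r, cc) (r + cc) / 16)
  gg <- imageGradients(flat45)
  expect_equal(gg$orientation[4, 4], 45, tolerance = 1e-9)
  expect_true(all(gg$orientation >= 0 & gg$orientation < 180))
  expect_error(imageGradients(matrix(0, 2, 2)), "3x3")
})

test_that("HOG descriptor has the fixed 3780 layout", {
  expect_length(hogDescriptor(wavyImage()), 3780L)
  expect_length(hogDescriptor(matrix(runif(50 * 70), 50, 70)), 3780L)
  expect_equal(hogDescriptor(matrix(0.7, 128, 64)), rep(0, 3780))
})

test_that("a vertical step edge concentrates mass in the 0-degree bin", {
  img <- matrix(0, 128, 64)
  img[, 33:64] <- 1                    # step along columns -> gx only
  d <- hogDescriptor(img)
  blocks <- matrix(d, nrow = 36)       # 36 values per block, 105 blocks
  # blocks covering the edge (cell cols 4|5 -> block col 4) carry energy
  energetic <- which(colSums(blocks) > 0.5)
  expect_gt(length(energetic), 0)
  for (b in energetic) {
    cellHists <- matrix(blocks[, b], nrow = 9)
    hot <- cellHists[, colSums(cellHists) > 1e-6, drop = FALSE]
    expect_true(all(apply(hot, 2, which.max) == 1L))  # bin centered at 0
  }
})

test_that("LBP codes follow the strict-comparison definition", {
  p <- matrix(5, 3, 3)
  p[2, 2] <- 5
  expect_equal(lbpCode(p), 0L)         # ties code as 0
  expect_equal(lbpCode(matrix(c(6, 6, 6, 6, 5, 6, 6, 6, 6), 3, 3)), 255L)
  expect_equal(lbpCode(matrix(c(4, 4, 4, 4, 5, 4, 4, 4, 4), 3, 3)), 0L)
  corner <- matrix(5, 3, 3); corner[1, 1] <- 7   # top-left => bit 0
  expect_equal(lbpCode(corner), 1L)
})

test_that("uniform LBP histogram has 59 bins and unit mass", {
  h <- lbpHistogram(matrix(0.4, 16, 16))
  expect_length(h, 59L)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_equal(sum(h > 0), 1L)          # constant image -> one bin
  h2 <- lbpHistogram(wavyImage())
  expect_equal(sum(h2), 1, tolerance = 1e-12)
})

test_that("the uniform-pattern count matches exhaustive enumeration", {
  # independent oracle over all 256 codes via string rotation
  transitions <- vapply(0:255, function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(bits != c(bits[-1], bits[1]))
  }, integer(1))
  expect_equal(sum(transitions <= 2), 58L)
})

test_that("LBP is invariant to global additive shifts", {
  img <- wavyImage() * 0.5
  expect_equal(lbpHistogram(img), lbpHistogram(img + 0.2), tolerance = 1e-12)
})

test_that("SURF finds a centered blob and nothing on flat input", {
  expect_equal(nrow(surfKeypoints(matrix(0.5, 32, 32))), 0L)
  r <- matrix(seq_len(64), 64, 64); cc <- t(r)
  blob <- 0.2 + 0.6 * exp(-((r - 32)^2 + (cc - 32)^2) / (2 * 4^2))
  kp <- surfKeypoints(blob)
  expect_gt(nrow(kp), 0L)
  best <- kp[which.max(kp$detH), ]
  expect_lte(abs(best$row - 32), 3)
  expect_lte(abs(best$col - 32), 3)
  expect_error(surfKeypoints(matrix(0.5, 8, 8)), "16x16")
})

test_that("SURF summary has the fixed 13-slot layout", {
  expect_equal(surfSummary(matrix(0.5, 32, 32)), numeric(13L))
  r <- matrix(seq_len(64), 64, 64); cc <- t(r)
  blob <- 0.2 + 0.6 * exp(-((r - 32)^2 + (cc - 32)^2) / (2 * 4^2))
  kp <- surfKeypoints(blob)
  s <- surfSummary(blob, kp)
  expect_length(s, 13L)
  expect_equal(s[1], nrow(kp))
  # a forced keypoint on a constant image has zero Haar responses
  fake <- data.frame(row = 16, col = 16, scale = 1.2, detH = 1)
  s0 <- surfSummary(matrix(0.3, 32, 32), fake)
  # integral-image cumsums leave ~1e-12 float residue
  expect_equal(s0[5:12], rep(0, 8), tolerance = 1e-9)
})

test_that("hybrid fusion is lossless with a correct span manifest", {
  hog <- runif(3780); surf <- runif(13); lbp <- runif(59)
  fv <- fuseHFE(hog, surf, lbp)
  expect_length(featureValues(fv), 3852L)
  expect_equal(featureValues(fv), c(hog, surf, lbp))
  sp <- featureSpans(fv)
  expect_equal(sp$hog, c(0L, 3780L))
  expect_equal(sp$surf, c(3780L, 3793L))
  expect_equal(sp$lbp, c(3793L, 3852L))
  expect_error(fuseHFE(runif(100), surf, lbp), "3780")
  z <- fuseHFE(rep(0, 3780), rep(0, 13), rep(0, 59))
  expect_true(all(featureValues(z) == 0))
})
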