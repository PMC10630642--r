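test_that("zero-perturbation mask is the discrete circle / ellipse", {
  cs <- circleScene(radius = 10)
  mask <- generateLesionMask(cs$spec, cs$scene)
  r <- matrix(seq_len(128), 128, 128) - 64
  cc <- matrix(seq_len(128), 128, 128, byrow = TRUE) - 64
  oracle <- sqrt((r / 10)^2 + (cc / 10)^2) <= 1
  expect_identical(mask, oracle)
})

test_that("masks are deterministic under a fixed seed", {
  scene <- sceneSpec(seed = 11L)
  spec <- lesionSpec(radii = c(14, 18), borderIrregularity = 0.3,
                     nHarmonics = 5L)
  expect_identical(generateLesionMask(spec, scene),
                   generateLesionMask(spec, scene))
})

test_that("perturbed mask area stays within 25% of the base ellipse", {
  scene <- sceneSpec(seed = 1L)
  base <- lesionSpec(radii = c(10, 10))
  pert <- lesionSpec(radii = c(10, 10), borderIrregularity = 0.3,
                     nHarmonics = 5L)
  a0 <- sum(generateLesionMask(base, scene))
  a1 <- sum(generateLesionMask(pert, scene))
  expect_lt(abs(a1 - a0) / a0, 0.25)
})

test_that("rendered masks are a single 4-connected component", {
  for (seed in 1:3) {
    scene <- sceneSpec(seed = seed)
    spec <- lesionSpec(radii = c(12, 17), borderIrregularity = 0.4,
                       nHarmonics = 8L)
    mask <- generateLesionMask(spec, scene)
    lab <- EBImage::bwlabel(mask)
    expect_equal(max(lab), 1)
  }
})

test_that("a lesion that does not fit is rejected with a sizing error", {
  scene <- sceneSpec(height = 64L, width = 64L)
  expect_error(generateLesionMask(lesionSpec(center = c(32, 32),
                                             radii = c(40, 10)), scene),
               "exceeds the frame")
})

test_that("clean render matches the level map and contrast invariant", {
  cs <- circleScene(radius = 12)
  img <- cs$image
  expect_true(all(img >= 0 & img <= 1))
  expect_lt(abs(img[64, 64] - cs$spec$lesionLevel), 0.02)
  expect_lt(mean(img[cs$mask]), mean(img[!cs$mask]))
})

test_that("speckle follows the multiplicative law I = G(1 + eta)", {
  g <- matrix(0.5, 256, 256)
  expect_identical(addSpeckle(g, 0), g)
  expect_error(addSpeckle(g, -0.1), "nonnegative")
  i <- addSpeckle(g, 0.2, seed = 7L)
  expect_lt(abs(mean(i) - 0.5), 0.01)             # E[I] = G
  expect_lt(abs(sd(i / g - 1) - 0.2), 0.01)       # sd of eta
  expect_identical(i, addSpeckle(g, 0.2, seed = 7L))
})

test_that("generated datasets are balanced, reproducible and separated", {
  ds <- makeDermoDataset(10, scene = sceneSpec(seed = 3L))
  man <- attr(ds, "manifest")
  expect_length(ds, 20L)
  expect_equal(as.vector(table(man$label)), c(10L, 10L))
  man2 <- attr(makeDermoDataset(10, scene = sceneSpec(seed = 3L)), "manifest")
  expect_identical(man, man2)
  irr <- tapply(man$border_irregularity, man$label, mean)
  expect_gt(irr[["melanoma"]], irr[["non_melanoma"]])
})

test_that("shape statistics linearly separate the two classes", {
  ds <- makeDermoDataset(100, scene = sceneSpec(seed = 1L))
  st <- t(vapply(ds, function(r) lesionShapeStats(r$image, r$mask),
                 numeric(3)))
  y <- factor(vapply(ds, `[[`, "", "label"))
  fit <- suppressWarnings(
    glm(y ~ ., data = data.frame(st, y = y), family = binomial))
  acc <- mean((predict(fit, type = "response") > 0.5) ==
                (y == "non_melanoma"))
  expect_gt(acc, 0.9)
})

test_that("dataset writing round-trips images through PNG", {
  dir <- withr::local_tempdir()
  ds <- makeDermoDataset(2, scene = sceneSpec(seed = 5L))
  writeDermoDataset(ds, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4L)
  back <- readGrayImage(file.path(dir, man$filename[1]))
  expect_equal(dim(back), dim(ds[[1]]$image))
  expect_lt(max(abs(back - ds[[1]]$image)), 1 / 255)  # 8-bit quantization
})
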