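test_that("structure tensor matches a brute-force eigensolve oracle", {
  set.seed(2)
  for (sigma in c(1, 1.5)) {
    ch <- matrix(runif(81), 9, 9)
    got <- structureTensorEigen(ch, sigma = sigma)
    ref <- bruteTensorEigen(ch, sigma = sigma)
    expect_lt(max(abs(got$lambdaMax - ref$lambdaMax)), 1e-10)
    expect_lt(max(abs(got$lambdaMin - ref$lambdaMin)), 1e-10)
  }
  ## also on the 8-bit intensity scale (larger magnitudes)
  ch <- matrix(runif(81) * 255, 9, 9)
  got <- structureTensorEigen(ch, sigma = 1)
  ref <- bruteTensorEigen(ch, sigma = 1)
  expect_lt(max(abs(got$lambdaMax - ref$lambdaMax)), 1e-8)
})

test_that("structure tensor on degenerate inputs is analytic", {
  ev <- structureTensorEigen(matrix(7, 12, 12))
  expect_true(all(ev$lambdaMax == 0) && all(ev$lambdaMin == 0))
  ## unit ramp along x: interior eigenpair is (1, 0)
  rp <- matrix(rep(1:30, each = 30), 30, 30)
  ev <- structureTensorEigen(rp, sigma = 1)
  inner <- 6:25
  expect_equal(ev$lambdaMax[inner, inner],
               matrix(1, 20, 20), tolerance = 1e-12)
  expect_equal(ev$lambdaMin[inner, inner],
               matrix(0, 20, 20), tolerance = 1e-12)
  expect_error(structureTensorEigen(matrix(c(NA, 1:8), 3, 3)), "finite")
})

test_that("eigenvalue maps are PSD-ordered and offset-invariant", {
  set.seed(4)
  ch <- matrix(runif(400) * 255, 20, 20)
  ev <- structureTensorEigen(ch)
  expect_true(all(ev$lambdaMax >= ev$lambdaMin))
  expect_true(all(ev$lambdaMin >= -1e-9))
  ev2 <- structureTensorEigen(ch + 40)
  expect_equal(ev$lambdaMax, ev2$lambdaMax, tolerance = 1e-9)
})

test_that("local entropy matches a brute-force histogram oracle", {
  set.seed(3)
  ch <- matrix(floor(runif(144) * 256), 12, 12)
  for (r in c(2, 4)) {
    got <- localEntropy(ch, r = r)
    ref <- bruteEntropy(ch, r = r)
    expect_lt(max(abs(got - ref)), 1e-10)
  }
  ## coarse binning
  got <- localEntropy(ch, r = 2, nBins = 8)
  ref <- bruteEntropy(ch, r = 2, nBins = 8)
  expect_lt(max(abs(got - ref)), 1e-10)
})

test_that("entropy is analytic on constant and two-valued patches", {
  expect_true(all(localEntropy(matrix(50, 10, 10), r = 3) == 0))
  ## checkerboard: a radius-2 disc holds 13 pixels, 9 matching the centre
  ## parity and 4 not -> binary entropy H(9/13)
  cb <- 255 * outer(1:12, 1:12, function(i, j) (i + j) %% 2)
  h <- localEntropy(cb, r = 2)
  p <- 9 / 13
  expect_equal(h[6, 6], -p * log2(p) - (1 - p) * log2(1 - p),
               tolerance = 1e-12)
  ## bounded by log2(nBins)
  set.seed(5)
  ch <- matrix(runif(400) * 255, 20, 20)
  expect_true(all(localEntropy(ch, r = 4, nBins = 16) <= 4 + 1e-12))
  expect_error(localEntropy(ch, r = 15), "radius")
})

test_that("feature stack has the documented 24-plane contract", {
  g <- generateMicrograph(syntheticImageParams(width = 64, height = 64,
                                               seed = 11))
  fs <- buildFeatureStack(g$micrograph)
  expect_identical(dim(featureArray(fs)), c(64L, 64L, 24L))
  expect_length(featureNames(fs), 24L)
  expect_identical(featureNames(fs)[1:4],
                   c("R.intensity", "R.lambdaMax", "R.lambdaMin",
                     "R.entropy"))
  expect_identical(featureNames(fs)[21:24],
                   c("V.intensity", "V.lambdaMax", "V.lambdaMin",
                     "V.entropy"))
  expect_error(buildFeatureStack(matrix(1, 64, 64)), "RGB")
})

test_that("tensor features are equivariant to 90-degree rotation", {
  g <- generateMicrograph(syntheticImageParams(width = 64, height = 64,
                                               seed = 13))
  ch <- pixelData(g$micrograph)[, , 1]
  rot90 <- function(m) t(m)[, nrow(m):1]  # counter-clockwise
  evA <- structureTensorEigen(ch, sigma = 2)
  evB <- structureTensorEigen(rot90(ch), sigma = 2)
  inner <- 10:55
  expect_equal(rot90(evA$lambdaMax)[inner, inner],
               evB$lambdaMax[inner, inner], tolerance = 1e-9)
  expect_equal(rot90(evA$lambdaMin)[inner, inner],
               evB$lambdaMin[inner, inner], tolerance = 1e-9)
})

test_that("features are translation-equivariant in the interior", {
  g <- generateMicrograph(syntheticImageParams(width = 64, height = 64,
                                               seed = 17))
  ch <- pixelData(g$micrograph)[, , 2]
  sh <- ch[, c(4:64, 1:3)]  # shift left by 3
  evA <- structureTensorEigen(ch, sigma = 2)
  evB <- structureTensorEigen(sh, sigma = 2)
  expect_equal(evA$lambdaMax[20:45, 23:50], evB$lambdaMax[20:45, 20:47],
               tolerance = 1e-9)
  enA <- localEntropy(ch, r = 3)
  enB <- localEntropy(sh, r = 3)
  expect_equal(enA[20:45, 23:50], enB[20:45, 20:47], tolerance = 1e-12)
})
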