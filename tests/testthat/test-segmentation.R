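test_that("training-pixel sampling is balanced, clamped and seeded", {
  fx <- standardFixture()
  tr <- sampleTrainingPixels(fx$stack, fx$mask, nPerClass = 100, seed = 3)
  expect_identical(as.integer(table(tr$labels)), rep(100L, 4))
  expect_identical(nrow(tr$features), 400L)
  tr2 <- sampleTrainingPixels(fx$stack, fx$mask, nPerClass = 100, seed = 3)
  expect_identical(tr$features, tr2$features)
  ## clamping: request more pixels than one class has
  small <- fx$mask
  avail <- sum(small == 3L)
  expect_warning(
    trc <- sampleTrainingPixels(fx$stack, small, nPerClass = avail + 50,
                                seed = 1),
    "available")
  expect_identical(sum(trc$labels == 3L), avail)
  ## strict mode rejects a missing class
  nomask <- matrix(0L, 96, 96); nomask[1:40, ] <- 1L; nomask[60:96, ] <- 2L
  expect_error(sampleTrainingPixels(fx$stack, nomask, 10, seed = 1),
               "missing classes: 3")
})

test_that("classifier training is seeded and enforces its contracts", {
  fx <- noiselessFixture()
  ## resubstitution on separable data is perfect
  pr <- predict(fx$model@forest, data = as.data.frame(fx$train$features),
                num.threads = 1)$predictions
  lev <- as.integer(colnames(pr))
  pred <- lev[max.col(pr, ties.method = "first")]
  expect_equal(pred, fx$train$labels)
  ## same data and seed give identical held-out predictions
  m2 <- trainClassifier(fx$train, nTrees = 100, seed = 2)
  mapsA <- predictProbabilityMaps(fx$model, fx$stack)
  mapsB <- predictProbabilityMaps(m2, fx$stack)
  expect_identical(probMaps(mapsA), probMaps(mapsB))
  ## single-class training set is rejected
  one <- fx$train
  one$labels[] <- 1L
  expect_error(trainClassifier(one), "single class")
  ## mismatched feature names are rejected
  stack2 <- fx$stack
  stack2@featureNames <- rev(featureNames(stack2))
  expect_error(predictProbabilityMaps(fx$model, stack2), "feature names")
})

test_that("probability maps normalize and concentrate on separable data", {
  fx <- noiselessFixture()
  maps <- predictProbabilityMaps(fx$model, fx$stack)
  s <- apply(probMaps(maps), c(1, 2), sum)
  expect_lt(max(abs(s - 1)), 1e-9)
  ## deep-interior collagen pixels get >= 0.9 collagen probability
  m <- probMaps(maps)
  bin <- matrix(as.numeric(fx$mask == 1L), 64, 64)
  interior <- EBImage::imageData(EBImage::erode(bin,
                                                EBImage::makeBrush(9,
                                                                   "disc")))
  idx <- which(interior > 0)
  expect_gt(length(idx), 0)
  expect_gte(stats::median(m[, , 2][idx]), 0.9)
  ## end-to-end: predicted mask matches truth on >= 99% of pixels
  pred <- classifyPixels(maps)
  expect_gte(mean(pred == fx$mask), 0.99)
})

test_that("argmax labelling breaks ties toward the lowest label", {
  maps <- array(0, c(1, 1, 4))
  maps[1, 1, ] <- c(0.1, 0.7, 0.1, 0.1)
  expect_identical(classifyPixels(maps)[1, 1], 1L)
  maps[1, 1, ] <- c(0.5, 0.5, 0, 0)
  expect_identical(classifyPixels(maps)[1, 1], 0L)
  ## scale invariance
  set.seed(8)
  m <- array(runif(2 * 3 * 4), c(2, 3, 4))
  expect_identical(classifyPixels(m), classifyPixels(m * 3.7))
})

test_that("threshold banding follows the cut points", {
  img <- array(50, c(8, 8, 3))
  expect_true(all(thresholdSegment(img, 100) == 0L))
  two <- array(40, c(8, 8, 3)); two[, 5:8, ] <- 200
  seg <- thresholdSegment(two, 120)
  expect_identical(as.integer(table(seg)), c(32L, 32L))
  expect_true(all(seg[, 1:4] == 0L) && all(seg[, 5:8] == 1L))
  expect_error(thresholdSegment(img, c(100, 90)), "increasing")
  expect_error(thresholdSegment(img, c(10, 20, 30, 40)), "thresholds")
})

test_that("confusion metrics agree with hand-computed cases", {
  ## diagonal matrix: perfect scores
  d <- diag(c(10, 20, 30, 40))
  r <- confusionAndMetrics(d)
  expect_equal(r$accuracy, 1)
  expect_true(all(r$perClass$precision == 1) && all(r$perClass$mcc == 1))
  expect_true(all(r$perClass$fp_rate == 0))
  ## hand-computed 2-class case embedded in the 4-class layout:
  ## TP=8, FN=2, FP=1, TN=9 for class 1
  truth <- matrix(c(rep(1L, 10), rep(0L, 10)), 4, 5)
  pred <- truth
  pred[truth == 1L][1:2] <- 0L   # 2 false negatives
  pred[truth == 0L][1] <- 1L     # 1 false positive
  r2 <- confusionAndMetrics(truth, pred)
  i <- which(r2$perClass$class == "collagen")
  expect_equal(r2$perClass$precision[i], 8 / 9, tolerance = 1e-12)
  expect_equal(r2$perClass$recall[i], 0.8, tolerance = 1e-12)
  mccExp <- (8 * 9 - 1 * 2) / sqrt(9 * 10 * 10 * 11)
  expect_equal(r2$perClass$mcc[i], mccExp, tolerance = 1e-12)
  expect_equal(mccExp, 0.7035, tolerance = 1e-4)
  ## zero-denominator cells are flagged zeros, not NaN
  z <- matrix(0, 4, 4); z[1, 1] <- 5
  rz <- confusionAndMetrics(z)
  expect_false(any(is.nan(as.matrix(rz$perClass[, 3:8]))))
  expect_true(any(rz$perClass$flagged == 1))
  expect_error(confusionAndMetrics(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               "shape")
})

test_that("metrics are permutation-consistent under relabelling", {
  set.seed(21)
  truth <- matrix(sample(0:3, 400, replace = TRUE), 20, 20)
  pred <- truth
  pred[sample(400, 60)] <- sample(0:3, 60, replace = TRUE)
  r <- confusionAndMetrics(truth, pred)
  perm <- c(2L, 3L, 0L, 1L)   # relabel map old -> new
  r2 <- confusionAndMetrics(matrix(perm[truth + 1L], 20, 20),
                            matrix(perm[pred + 1L], 20, 20))
  expect_equal(r2$perClass$mcc[perm + 1L], r$perClass$mcc)
  expect_equal(r2$accuracy, r$accuracy)
})

test_that("cross-validation is stratified, pooled and deterministic", {
  fx <- noiselessFixture()
  cv1 <- crossValidate(fx$train, k = 10, seed = 4, nTrees = 60)
  expect_gte(cv1$accuracy, 0.99)
  expect_equal(sum(cv1$confusion), length(fx$train$labels))
  cv2 <- crossValidate(fx$train, k = 10, seed = 4, nTrees = 60)
  expect_identical(cv1$confusion, cv2$confusion)
  ## leave-one-out on a small subset runs and returns valid metrics
  idx <- c(1:5, 121:125, 241:245, 361:365)
  small <- structure(list(features = fx$train$features[idx, ],
                          labels = fx$train$labels[idx],
                          coords = fx$train$coords[idx, ],
                          featureNames = fx$train$featureNames, seed = 1L),
                     class = "trainingSet")
  cvLoo <- suppressWarnings(crossValidate(small, k = 20, seed = 1,
                                          nTrees = 30))
  expect_true(is.finite(cvLoo$accuracy))
})

test_that("misclassification error is the root of the discordance count", {
  a <- matrix(0L, 10, 10)
  expect_equal(misclassificationError(a, a, 1), 0)
  b <- a; b[1:25] <- 1L
  expect_equal(misclassificationError(a, b, 1), 5)
  ## brute-force agreement on random masks
  set.seed(6)
  t1 <- matrix(sample(0:3, 10000, TRUE), 100, 100)
  p1 <- matrix(sample(0:3, 10000, TRUE), 100, 100)
  for (cls in 0:3) {
    cnt <- 0
    for (i in 1:100) for (j in 1:100)
      if ((t1[i, j] == cls) != (p1[i, j] == cls)) cnt <- cnt + 1
    expect_equal(misclassificationError(t1, p1, cls), sqrt(cnt))
  }
})
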