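test_that("penalized spline reproduces linear data exactly", {
  x <- 0:44
  y <- 2 + 0.5 * x
  fit <- fitGam(x, y)
  expect_lt(max(abs(fit$fitted - y)), 1e-6)
  expect_equal(fit$rSquared, 1, tolerance = 1e-9)
})

test_that("penalized spline tracks a smooth two-sigmoid curve", {
  x <- seq(0, 44, by = 0.5)
  y <- mixturePredict(x, c(45, 6, 2.5, 25, 28, 3.5))
  fit <- fitGam(x, y, L = 15)
  expect_lt(max(abs(fit$fitted - y)) / diff(range(y)), 0.01)
  expect_gt(fit$rSquared, 0.999)
  ## predictions interpolate the fitted curve
  expect_equal(predict(fit, x), fit$fitted, tolerance = 1e-9)
})

test_that("spline basis size, degeneracy and robustness contracts hold", {
  x <- 0:44
  fit <- fitGam(x, sin(x / 7))
  expect_length(fit$beta, 10 + 3)      # L + degree basis functions
  expect_error(fitGam(rep(1:5, 4), rnorm(20)), "reduce L")
  ## duplicated x with jitter still yields a finite fit
  xd <- rep(0:21, each = 2)
  set.seed(9)
  fit2 <- fitGam(xd, 0.3 * xd + rnorm(44, 0, 0.1), L = 8)
  expect_true(all(is.finite(fit2$fitted)))
  ## GCV selected a positive smoothing value from the grid
  expect_true(fit$lambda %in% fit$gcvTable$lambda)
})

test_that("spline fit is invariant to affine rescaling of time", {
  x <- 0:44
  y <- mixturePredict(x, c(45, 6, 2.5, 25, 28, 3.5))
  f1 <- fitGam(x, y)
  f2 <- fitGam(10 + 2.5 * x, y)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-6)
})

test_that("penalized spline agrees with an established P-spline fit", {
  skip_if_not_installed("mgcv")
  set.seed(14)
  x <- seq(0, 44, length.out = 90)
  y <- mixturePredict(x, thetaCCO) + rnorm(90, 0, 1)
  ours <- fitGam(x, y, L = 10)
  ref <- mgcv::gam(y ~ s(x, bs = "ps", k = 13, m = c(2, 2)))
  expect_lt(max(abs(ours$fitted - stats::fitted(ref))) / diff(range(y)),
            0.05)
})

test_that("linear fits recover printed-model coefficients exactly", {
  ## univariate: mass loss against ln(area)
  set.seed(3)
  area <- runif(21, 100, 4000)
  yA <- -5.217 + 10.578 * log(area)
  fitA <- fitLinear(y ~ log(area), data.frame(area = area, y = yA))
  expect_equal(fitA$coefTable$estimate, c(-5.217, 10.578),
               tolerance = 1e-10)
  ## mass loss against ln(circularity)
  circ <- runif(21, 0.05, 0.9)
  yC <- -19.4 - 14.9 * log(circ)
  fitC <- fitLinear(y ~ log(circ), data.frame(circ = circ, y = yC))
  expect_equal(fitC$coefTable$estimate, c(-19.4, -14.9), tolerance = 1e-10)
  ## slope-only sanity: y = 2x
  x <- 1:10
  fit2 <- fitLinear(y ~ x, data.frame(x = x, y = 2 * x))
  expect_equal(fit2$coefTable$estimate[2], 2, tolerance = 1e-12)
  expect_equal(fit2$rSquared, 1)
})

test_that("multivariate refit recovers the full coefficient vector", {
  tab <- simulateFeatureTable(multivarCoefs, nPerGroup = 20, noiseSd = 0,
                              seed = 2)
  fit <- fitLinear(mass_loss_pct ~ group + log(mean_circularity) +
                     log(gray_mode) + log(mean_area_um2), tab)
  est <- fit$coefTable$estimate
  names(est) <- fit$coefTable$term
  expect_equal(unname(est["(Intercept)"]), -17.0396, tolerance = 1e-8)
  expect_equal(unname(est["groupCCT"]), -0.215, tolerance = 1e-8)
  expect_equal(unname(est["groupCO"]), -2.1751, tolerance = 1e-8)
  expect_equal(unname(est["log(mean_circularity)"]), -0.0599,
               tolerance = 1e-8)
  expect_equal(unname(est["log(gray_mode)"]), 3.7804, tolerance = 1e-8)
  expect_equal(unname(est["log(mean_area_um2)"]), 0.1760, tolerance = 1e-8)
})

test_that("linear-fit validation errors name the offender", {
  d <- data.frame(x = c(1, 2, -3, 4), y = 1:4)
  ## log(-3) itself warns before the contract error fires
  suppressWarnings(expect_error(fitLinear(y ~ log(x), d), "row 3"))
  d2 <- data.frame(x = 1:10, z = 2 * (1:10), y = rnorm(10))
  expect_error(fitLinear(y ~ x + z, d2), "aliased.*z")
})

test_that("lmg shares decompose R-squared over orderings", {
  ## correlated 3-predictor table vs brute-force enumeration of orderings
  set.seed(7)
  n <- 60
  x1 <- rnorm(n); x2 <- 0.6 * x1 + rnorm(n); x3 <- rnorm(n)
  y <- 1 + 2 * x1 - x2 + 0.5 * x3 + rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2, x3 = x3, y = y)
  fit <- fitLinear(y ~ x1 + x2 + x3, d)
  got <- relativeImportanceLMG(fit)
  ## oracle: average incremental R-squared over the 6 explicit orderings
  r2of <- function(vars) {
    if (!length(vars)) return(0)
    f <- stats::as.formula(paste("y ~", paste(vars, collapse = " + ")))
    m <- stats::lm(f, d)
    1 - sum(stats::residuals(m)^2) / sum((y - mean(y))^2)
  }
  preds <- c("x1", "x2", "x3")
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  oracle <- stats::setNames(numeric(3), preds)
  for (pm in perms) {
    for (pos in seq_along(pm)) {
      j <- pm[pos]
      oracle[j] <- oracle[j] +
        (r2of(preds[pm[seq_len(pos)]]) -
           r2of(preds[pm[seq_len(pos - 1)]])) / length(perms)
    }
  }
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_equal(sum(got), fit$rSquared, tolerance = 1e-9)
})

test_that("orthogonal predictors get their marginal R-squared as share", {
  ## balanced +-1 design columns are exactly orthogonal
  x1 <- rep(c(-1, 1), each = 8)
  x2 <- rep(c(-1, 1), times = 8)
  y <- 3 * x1 + 1 * x2
  d <- data.frame(x1 = x1, x2 = x2, y = y)
  fit <- fitLinear(y ~ x1 + x2, d)
  got <- relativeImportanceLMG(fit)
  marg1 <- summary(stats::lm(y ~ x1, d))$r.squared
  marg2 <- summary(stats::lm(y ~ x2, d))$r.squared
  expect_equal(unname(got["x1"]), marg1, tolerance = 1e-10)
  expect_equal(unname(got["x2"]), marg2, tolerance = 1e-10)
  expect_true(all(got >= 0))
})

test_that("k-fold predictions are seeded and exact for on-model data", {
  tab <- simulateFeatureTable(multivarCoefs, nPerGroup = 20, noiseSd = 0,
                              seed = 4)
  form <- mass_loss_pct ~ group + log(mean_circularity) + log(gray_mode) +
    log(mean_area_um2)
  cv <- kfoldPredictions(form, tab, k = 3, seed = 5)
  expect_equal(cv$observed, cv$predicted, tolerance = 1e-8)
  cv2 <- kfoldPredictions(form, tab, k = 3, seed = 5)
  expect_identical(cv$fold, cv2$fold)
  ## noisy on-model data keep high observed-predicted correlation
  tabN <- simulateFeatureTable(multivarCoefs, nPerGroup = 20, noiseSd = 0.5,
                               seed = 6)
  cvN <- kfoldPredictions(form, tabN, k = 3, seed = 7)
  expect_gt(stats::cor(cvN$observed, cvN$predicted), 0.9)
})
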