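test_that("logistic and Gompertz curves are analytic at landmarks", {
  ## midpoint: y(mu) = A/2, with the published first CCO component
  expect_equal(logisticCurve(1.734, A = 50.223, mu = 1.734, scal = 1),
               25.1115)
  expect_equal(logisticCurve(-1e9, 10, 0, 2), 0, tolerance = 1e-12)
  expect_equal(logisticCurve(1e9, 10, 0, 2), 10, tolerance = 1e-12)
  expect_equal(logisticCurve(2, 10, 0, 2), 10 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_error(logisticCurve(1, 10, 0, -1), "scal")
  ## Gompertz: y(lambda) = A exp(-e)
  expect_equal(gompertzCurve(1, A = 100, mu = 3, lambda = 1),
               100 * exp(-exp(1)), tolerance = 1e-12)
  expect_equal(gompertzCurve(1e9, 100, 3, 1), 100, tolerance = 1e-9)
  expect_equal(gompertzCurve(3, A = 10, mu = 2, lambda = 1),
               10 * exp(-exp((2 * exp(1) / 10) * (1 - 3) + 1)),
               tolerance = 1e-12)
  expect_error(gompertzCurve(1, A = -1, mu = 2, lambda = 1), "A")
})

test_that("mixture prediction is the explicit component sum", {
  t <- seq(0, 44, length.out = 20)
  ## k = 1 reduces to the single logistic
  expect_equal(mixturePredict(t, c(10, 5, 2)),
               logisticCurve(t, 10, 5, 2), tolerance = 1e-15)
  ## matches an independent two-term sum for random parameters
  set.seed(12)
  for (rep in 1:5) {
    th <- c(runif(1, 10, 60), runif(1, 0, 20), runif(1, 0.5, 5),
            runif(1, 10, 60), runif(1, 20, 44), runif(1, 0.5, 5))
    manual <- th[1] / (1 + exp((th[2] - t) / th[3])) +
      th[4] / (1 + exp((th[5] - t) / th[6]))
    expect_equal(mixturePredict(t, th), manual, tolerance = 1e-14)
  }
  ## monotone nondecreasing; limit is the summed asymptotes
  y <- mixturePredict(seq(-50, 150, by = 0.5), thetaCCO)
  expect_true(all(diff(y) >= 0))
  expect_equal(mixturePredict(1e8, thetaCCO), 73.686, tolerance = 1e-9)
  expect_error(mixturePredict(1, c(1, 2)), "3k")
})

test_that("Kvalseth R-squared follows its defining identity", {
  y <- c(1, 2, 3)
  expect_equal(rSquaredKvalseth(y, y), 1)
  expect_equal(rSquaredKvalseth(y, c(1, 2, 4)), 0.5)
  expect_equal(rSquaredKvalseth(y, rep(mean(y), 3)), 0)
  expect_error(rSquaredKvalseth(rep(2, 5), rep(2, 5)), "constant")
})

test_that("noiseless single-logistic data are recovered exactly", {
  rec <- simulateMassLoss(c(40, 10, 3), times = 0:30, noiseSd = 0)
  fit <- fitMixture(rec, k = 1, seed = 2,
                    deControl = list(generations = 80))
  expect_equal(unname(fit$theta), c(40, 10, 3), tolerance = 1e-6)
  expect_equal(fit$rSquared, 1, tolerance = 1e-9)
})

test_that("component ordering and minimum data size are enforced", {
  rec <- simulateMassLoss(thetaCCO, times = 0:44, noiseSd = 0)
  fit <- fitMixture(rec, k = 2, seed = 5,
                    deControl = list(generations = 120))
  expect_lt(fit$theta[["mu_1"]], fit$theta[["mu_2"]])
  expect_identical(fit$coefTable$parameter,
                   c("A_1", "mu_1", "scal_1", "A_2", "mu_2", "scal_2"))
  expect_true(all(is.finite(fit$coefTable$std_error)))
  expect_error(fitMixture(rec[1:6, ], k = 2), "observations")
})

test_that("mu_2 is recovered within 10% median error at 2% noise", {
  ## Monte-Carlo recovery at the reported noise scale
  errs <- vapply(1:15, function(r) {
    rec <- simulateMassLoss(thetaCCO, times = 0:44,
                            noiseSd = 0.02 * 73.686, seed = 500 + r)
    f <- fitMixture(rec, k = 2, seed = 600 + r,
                    deControl = list(generations = 60, popSize = 30))
    abs(f$theta[["mu_2"]] - 16.261) / 16.261
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("bootstrap intervals are seeded, bracketing and noise-monotone", {
  rec <- simulateMassLoss(thetaCCO, times = 0:44, noiseSd = 0.7, seed = 31)
  fit <- fitMixture(rec, k = 2, seed = 32,
                    deControl = list(generations = 80, popSize = 30))
  b1 <- bootstrapParameters(fit, B = 120, seed = 33)
  b2 <- bootstrapParameters(fit, B = 120, seed = 33)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  expect_true(all(b1$lower <= b1$estimate + 1e-8))
  expect_true(all(b1$upper >= b1$estimate - 1e-8))
  ## vanishing noise collapses the intervals onto the estimates
  rec0 <- simulateMassLoss(thetaCCO, times = 0:44, noiseSd = 1e-8,
                           seed = 34)
  fit0 <- fitMixture(rec0, k = 2, seed = 35,
                     deControl = list(generations = 80, popSize = 30))
  b0 <- bootstrapParameters(fit0, B = 60, seed = 36)
  expect_lt(max(b0$upper - b0$lower), 1e-5)
  ## median width shrinks when noise shrinks
  widthAt <- function(sd, seedOff) {
    r <- simulateMassLoss(thetaCCO, times = 0:44, noiseSd = sd,
                          seed = 40 + seedOff)
    f <- fitMixture(r, k = 2, seed = 41 + seedOff,
                    deControl = list(generations = 60, popSize = 30))
    b <- bootstrapParameters(f, B = 80, seed = 42 + seedOff)
    stats::median(b$upper - b$lower)
  }
  expect_lt(widthAt(0.2, 0), widthAt(2, 10))
})
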