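## Sigmoid kinetic curves for percent mass loss and the Kvalseth coefficient
## of determination shared by every fit in the package.

#' Logistic growth curve
#'
#' `A / (1 + exp((mu - t) / scal))`: strictly increasing in `t`, equal to
#' `A/2` at the inflection time `mu`, with asymptote `A` and scale (inverse
#' rate) `scal` in days.
#'
#' @param t time in days (vectorised).
#' @param A asymptote (mass-loss percent), `A > 0`.
#' @param mu inflection time in days.
#' @param scal scale parameter in days, `scal > 0`.
#' @return Numeric vector of curve values.
#' @export
logisticCurve <- function(t, A, mu, scal) {
  if (any(scal <= 0)) stop("scal must be positive")
  if (any(A <= 0)) stop("A must be positive")
  A / (1 + exp((mu - t) / scal))
}

#' Gompertz growth curve
#'
#' `A * exp(-exp((mu*e/A) * (lambda - t) + 1))`, where `A` is the asymptote,
#' `mu` the maximum growth rate and `lambda` the lag before exponential
#' growth. At `t = lambda` the curve equals `A * exp(-e)` (about 6.6% of
#' `A`), and it tends to `A` as `t` grows.
#'
#' @param t time in days (vectorised).
#' @param A asymptote, `A > 0`.
#' @param mu maximum slope.
#' @param lambda lag time in days.
#' @return Numeric vector of curve values.
#' @export
gompertzCurve <- function(t, A, mu, lambda) {
  if (any(A <= 0)) stop("A must be positive")
  A * exp(-exp((mu * exp(1) / A) * (lambda - t) + 1))
}

#' Logistic-mixture mean curve
#'
#' The sum of `k` logistic components
#' `sum_i A_i / (1 + exp((mu_i - t)/scal_i))`; monotone nondecreasing in `t`
#' for positive scales, with `t -> Inf` limit `sum(A_i)`. Mixtures separate
#' overlapping degradation processes (for collagen scaffolds: an early
#' cell-independent process and a later, cell-driven one).
#'
#' @param t time in days (vectorised).
#' @param theta numeric vector of length `3k`:
#'   `(A1, mu1, scal1, ..., Ak, muk, scalk)`.
#' @return Numeric vector of mixture means.
#' @examples
#' thetaCCO <- c(50.223, 1.734, 1.000, 23.463, 16.261, 1.3233)
#' mixturePredict(1e6, thetaCCO)  # ~73.686, the summed asymptotes
#' @export
mixturePredict <- function(t, theta) {
  theta <- as.numeric(theta)
  if (length(theta) %% 3L != 0L || length(theta) == 0L)
    stop("theta must have length 3k for k >= 1 components")
  k <- length(theta) / 3L
  y <- numeric(length(t))
  for (i in seq_len(k)) {
    p <- theta[(3L * (i - 1L)) + 1:3]
    y <- y + logisticCurve(t, p[1], p[2], p[3])
  }
  y
}

#' Coefficient of determination (Kvalseth definition)
#'
#' `1 - SSE/SST = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Applies to
#' linear and nonlinear fits alike; at most 1, and negative when the fit is
#' worse than the constant mean.
#'
#' @param y observed values (length >= 2, non-constant).
#' @param yHat fitted values.
#' @return Scalar R-squared.
#' @export
rSquaredKvalseth <- function(y, yHat) {
  if (length(y) < 2L) stop("need at least two observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("y is constant; R-squared is undefined")
  1 - sum((y - yHat)^2) / sst
}
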