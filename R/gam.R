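## Penalized B-spline additive model (P-spline) of mass loss against time:
## equally spaced B-spline basis, second-order difference penalty, smoothing
## parameter chosen by generalized cross-validation over a logarithmic grid.

#' Fit a penalized B-spline smooth (GAM with one smooth term)
#'
#' Builds a B-spline basis of size `L + degree` on `L` equal-width segments
#' spanning the range of `x` (the P-spline construction), penalizes the
#' squared second-order differences of the coefficients, and for each
#' smoothing value `lambda` on a logarithmic grid solves the penalized least
#' squares problem
#' \deqn{\|y - B\beta\|^2 + \lambda\, \beta' D_2' D_2 \beta .}
#' The `lambda` minimising the generalized cross-validation score
#' `n * SSE / (n - edf)^2` is retained. Because the basis reproduces
#' polynomials up to the spline degree and the second-difference penalty
#' leaves linear coefficient sequences unpenalized, exactly linear data are
#' reproduced exactly at any `lambda`.
#'
#' @param x predictor (time in days); duplicated values are allowed provided
#'   the number of distinct values reaches the basis rank.
#' @param y response (percent mass loss).
#' @param L number of basis segments (default 10).
#' @param degree spline degree (default 3, cubic).
#' @param lambdaGrid numeric grid of candidate smoothing values; default 50
#'   points log-spaced in `[1e-6, 1e6]`.
#' @return Object of class `"gamFit"`: list with `beta`, `lambda`, `edf`,
#'   `fitted`, `rSquared`, `gcvTable` (lambda, gcv), `knots`, `degree`, `L`,
#'   and the data. Use [predict.gamFit()] for new `x`.
#' @export
fitGam <- function(x, y, L = 10, degree = 3,
                   lambdaGrid = 10^seq(-6, 6, length.out = 50)) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (L < 1 || degree < 1) stop("L and degree must be positive integers")
  p <- L + degree
  nDistinct <- length(unique(x))
  if (nDistinct < p)
    stop("only ", nDistinct, " distinct x values for a basis of rank ", p,
         "; reduce L")
  rng <- range(x)
  dx <- diff(rng) / L
  knots <- seq(rng[1] - degree * dx, rng[2] + degree * dx, by = dx)
  B <- splines::splineDesign(knots, x, ord = degree + 1, outer.ok = TRUE)
  D <- diff(diag(p), differences = 2)
  P <- crossprod(D)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)
  n <- length(y)
  best <- NULL
  gcvTab <- data.frame(lambda = lambdaGrid, gcv = NA_real_)
  for (i in seq_along(lambdaGrid)) {
    lam <- lambdaGrid[i]
    M <- BtB + lam * P
    beta <- solve(M, Bty)
    fitted <- drop(B %*% beta)
    ## edf = tr(B (B'B + lam P)^-1 B') = sum over elements of (B M^-1) * B
    edf <- sum(solve(M, t(B)) * t(B))
    sse <- sum((y - fitted)^2)
    gcv <- n * sse / (n - edf)^2
    gcvTab$gcv[i] <- gcv
    if (is.null(best) || gcv < best$gcv)
      best <- list(lambda = lam, beta = drop(beta), fitted = fitted,
                   edf = edf, gcv = gcv)
  }
  structure(list(beta = best$beta, lambda = best$lambda, edf = best$edf,
                 fitted = best$fitted,
                 rSquared = rSquaredKvalseth(y, best$fitted),
                 gcvTable = gcvTab, knots = knots, degree = degree, L = L,
                 x = x, y = y), class = "gamFit")
}

#' Predict from a fitted penalized spline
#'
#' @param object a `"gamFit"`.
#' @param newx new predictor values; values outside the training range are
#'   clipped to it (the basis has no support beyond its outer knots).
#' @param ... unused.
#' @return Numeric vector of fitted values.
#' @export
predict.gamFit <- function(object, newx = object$x, ...) {
  rng <- range(object$x)
  newx <- pmin(pmax(newx, rng[1]), rng[2])
  B <- splines::splineDesign(object$knots, newx, ord = object$degree + 1,
                             outer.ok = TRUE)
  drop(B %*% object$beta)
}

#' @export
print.gamFit <- function(x, ...) {
  cat("Penalized B-spline fit: ", x$L, " segments, degree ", x$degree,
      "\n", sep = "")
  cat("  lambda (GCV): ", signif(x$lambda, 4), "; edf: ",
      round(x$edf, 2), "; R-squared: ", round(x$rSquared, 4), "\n",
      sep = "")
  invisible(x)
}
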