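## Logistic-mixture fitting: seeded differential-evolution global search for
## starting values, Levenberg-Marquardt least-squares refinement, asymptotic
## significance analysis, and residual-bootstrap confidence intervals.

mixtureParNames <- function(k) {
  as.vector(vapply(seq_len(k), function(i)
    paste0(c("A_", "mu_", "scal_"), i), character(3)))
}

## SSE of a population of candidate parameter rows against (t, y).
mixtureSSEPop <- function(pop, t, y, k) {
  n <- length(t)
  pred <- matrix(0, nrow(pop), n)
  tm <- matrix(t, nrow(pop), n, byrow = TRUE)
  for (i in seq_len(k)) {
    A <- pop[, 3 * i - 2]; mu <- pop[, 3 * i - 1]; sc <- pop[, 3 * i]
    pred <- pred + A / (1 + exp((mu - tm) / sc))
  }
  rowSums((pred - matrix(y, nrow(pop), n, byrow = TRUE))^2)
}

## Reorder a (A, mu, scal) * k parameter vector by increasing mu.
sortComponents <- function(theta, k) {
  mus <- theta[3 * seq_len(k) - 1]
  ord <- order(mus)
  idx <- as.vector(vapply(ord, function(i) 3 * (i - 1) + 1:3, numeric(3)))
  list(theta = theta[idx], index = idx)
}

#' Fit a logistic mixture to mass-loss records
#'
#' Fits the `k`-component logistic mixture
#' `sum_i A_i / (1 + exp((mu_i - t)/scal_i))` to percent mass-loss
#' observations by minimising the residual sum of squares. Because the
#' objective is multimodal in the component parameters, a seeded
#' differential-evolution global search over the physical box first locates a
#' starting point, which Levenberg-Marquardt least squares then refines
#' (bounded). Components are reported sorted by inflection time so the fit is
#' identifiable; standard errors, t and p values come from the asymptotic
#' least-squares covariance, and goodness of fit is the Kvalseth R-squared.
#'
#' Default search box: asymptotes in `(0, 100]` (percent mass loss),
#' inflection times within the observed time range, scales in `[0.1, 20]`
#' days.
#'
#' @param records data frame with columns `time_days` and `mass_loss_pct`
#'   (as produced by [simulateMassLoss()]), or `time` may be given separately.
#' @param k number of logistic components (>= 1); at least `3k + 1`
#'   observations are required.
#' @param bounds list with elements `A`, `mu`, `scal`, each `c(lower,
#'   upper)`; `mu = NULL` defaults to the observed time range.
#' @param seed integer seed for the global search.
#' @param deControl list overriding the evolution settings `popSize`
#'   (default `10 * 3k`) and `generations` (default 300).
#' @return An object of class `"mixtureFit"`: list with `k`, `theta` (named,
#'   mu-sorted), `coefTable` (estimate, SE, t, p per parameter), `fitted`,
#'   `residuals`, `rSquared`, `convInfo`, `data`, `bounds`, `seed`.
#' @examples
#' rec <- simulateMassLoss(c(50, 2, 1, 25, 16, 1.5), times = 0:44,
#'                         noiseSd = 0)
#' fit <- fitMixture(rec, k = 2, deControl = list(generations = 60))
#' fit$theta
#' @export
fitMixture <- function(records, k = 2, bounds = list(A = c(1e-6, 100),
                                                     mu = NULL,
                                                     scal = c(0.1, 20)),
                       seed = 1L, deControl = list()) {
  if (is.data.frame(records)) {
    t <- records$time_days; y <- records$mass_loss_pct
  } else stop("records must be a data frame with time_days, mass_loss_pct")
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  n <- length(t)
  if (k < 1) stop("k must be >= 1")
  if (n < 3 * k + 1)
    stop("need at least 3k + 1 = ", 3 * k + 1, " observations")
  if (is.null(bounds$mu)) bounds$mu <- range(t)
  if (any(bounds$scal <= 0)) stop("scal bounds must be positive")
  lower <- rep(c(bounds$A[1], bounds$mu[1], bounds$scal[1]), k)
  upper <- rep(c(bounds$A[2], bounds$mu[2], bounds$scal[2]), k)

  ## global search for a starting point
  popSize <- deControl$popSize %||% (10L * 3L * k)
  generations <- deControl$generations %||% 300L
  de <- deOptim(function(p) mixtureSSEPop(p, t, y, k), lower, upper,
                popSize = popSize, generations = generations, seed = seed)
  start0 <- sortComponents(de$par, k)$theta
  ## keep the start strictly inside the box so the initial Jacobian is
  ## well conditioned
  pad <- 1e-3 * (upper - lower)
  start0 <- pmin(pmax(start0, lower + pad), upper - pad)

  ## bounded Levenberg-Marquardt refinement (jittered restarts on failure)
  pn <- mixtureParNames(k)
  terms <- vapply(seq_len(k), function(i) sprintf(
    "A_%d / (1 + exp((mu_%d - t) / scal_%d))", i, i, i), character(1))
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  dat <- data.frame(t = t, y = y)
  nlsFit <- NULL
  lastErr <- NULL
  jitters <- withSeed(seed, matrix(stats::rnorm(5 * length(start0), 0, 1),
                                   5))
  for (attempt in 0:5) {
    st <- if (attempt == 0) start0 else
      pmin(pmax(start0 * (1 + 0.1 * jitters[attempt, ]), lower + pad),
           upper - pad)
    nlsFit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat,
                        start = as.list(stats::setNames(st, pn)),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (!inherits(nlsFit, "error")) break
    lastErr <- nlsFit
  }
  if (inherits(nlsFit, "error")) nlsFit <- lastErr
  if (inherits(nlsFit, "error")) {
    cond <- simpleError(paste0("mixture fit did not converge: ",
                               conditionMessage(nlsFit)))
    cond$bestCandidate <- stats::setNames(start0, pn)
    cond$bestSSE <- de$value
    stop(cond)
  }
  theta <- stats::coef(nlsFit)
  srt <- sortComponents(unname(theta), k)
  theta <- stats::setNames(srt$theta, pn)
  sm <- summary(nlsFit)$coefficients
  se <- sm[srt$index, "Std. Error"]
  est <- theta
  tv <- est / se
  df <- n - 3 * k
  pv <- 2 * stats::pt(-abs(tv), df = max(df, 1))
  fitted <- mixturePredict(t, theta)
  structure(list(
    k = k, theta = theta,
    coefTable = data.frame(parameter = pn, estimate = unname(est),
                           std_error = unname(se), t_value = unname(tv),
                           p_value = unname(pv)),
    fitted = fitted, residuals = y - fitted,
    rSquared = rSquaredKvalseth(y, fitted),
    convInfo = list(deSSE = de$value,
                    finalSSE = sum((y - fitted)^2),
                    iterations = nlsFit$convInfo$finIter),
    data = dat, bounds = bounds, lower = lower, upper = upper,
    seed = seed), class = "mixtureFit")
}

#' @export
print.mixtureFit <- function(x, ...) {
  cat("Logistic mixture fit, k =", x$k, "\n")
  print(x$coefTable, row.names = FALSE, digits = 5)
  cat("R-squared (Kvalseth):", round(x$rSquared, 4), "\n")
  invisible(x)
}

#' Residual-bootstrap confidence intervals for mixture parameters
#'
#' Resamples mean-centred residuals with replacement, adds them to the
#' fitted curve, and refits the mixture from the point estimates (warm start;
#' the global search is not repeated). Percentile intervals at the requested
#' level are formed per parameter; refits that fail to converge are dropped
#' and counted, and more than 20% failures is an error.
#'
#' @param fit a `"mixtureFit"`.
#' @param B number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return Object of class `"bootstrapCI"`: data frame with `parameter`,
#'   `lower`, `estimate`, `upper` plus attributes `B`, `level`, `nFailed`,
#'   `seed`.
#' @export
bootstrapParameters <- function(fit, B = 1000, level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "mixtureFit"))
  k <- fit$k
  pn <- mixtureParNames(k)
  res <- fit$residuals - mean(fit$residuals)
  t <- fit$data$t
  start <- unname(fit$theta)
  draws <- withSeed(seed, {
    out <- matrix(NA_real_, B, 3 * k)
    for (b in seq_len(B)) {
      yb <- fit$fitted + sample(res, length(res), replace = TRUE)
      fb <- tryCatch(
        minpack.lm::nls.lm(par = start, lower = fit$lower,
                           upper = fit$upper,
                           fn = function(p) yb - mixturePredict(t, p),
                           control = minpack.lm::nls.lm.control(maxiter =
                                                                  200)),
        error = function(e) NULL)
      if (!is.null(fb) && fb$info %in% 1:4)
        out[b, ] <- sortComponents(unname(fb$par), k)$theta
    }
    out
  })
  okRows <- stats::complete.cases(draws)
  nFailed <- sum(!okRows)
  if (nFailed > 0.2 * B)
    stop("more than 20% of bootstrap refits failed (", nFailed, " of ", B,
         ")")
  if (nFailed > 0)
    warning(nFailed, " of ", B, " bootstrap refits failed and were dropped")
  a <- (1 - level) / 2
  qs <- apply(draws[okRows, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a), names = FALSE)
  out <- data.frame(parameter = pn, lower = qs[1, ],
                    estimate = unname(fit$theta), upper = qs[2, ])
  structure(out, B = B, level = level, nFailed = nFailed, seed = seed,
            class = c("bootstrapCI", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
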