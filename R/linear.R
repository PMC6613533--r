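## Linear models on log-transformed image features, relative-importance
## decomposition of R-squared (averaging over regressor orderings), and
## k-fold predictive validation.

#' Fit a linear model on (log-transformed) image features
#'
#' Ordinary least squares for formulas such as
#' `mass_loss_pct ~ group + log(mean_circularity) + log(gray_mode) +
#' log(mean_area_um2)`. Group factors are dummy-coded against the reference
#' level `CCO` (the first level) as in the multivariate mass-loss model.
#' Inputs feeding a `log()` must be strictly positive: any non-finite value
#' in the transformed design is an error naming the offending row. Exactly
#' collinear designs are rejected naming the aliased columns.
#'
#' @param formula model formula; write transforms (e.g. `log(x)`) directly.
#' @param data data frame with the referenced columns; a `group` column is
#'   releveled so `CCO` is the reference when present.
#' @return Object of class `"linearFit"`: list with `coefTable` (estimate,
#'   SE, t, p), `rSquared` (Kvalseth), `fitted`, `residuals`, the underlying
#'   `lm` object and the call ingredients.
#' @export
fitLinear <- function(formula, data) {
  data <- as.data.frame(data)
  if ("group" %in% names(data)) {
    lev <- unique(as.character(data$group))
    data$group <- factor(as.character(data$group),
                         levels = c(intersect("CCO", lev),
                                    setdiff(sort(lev), "CCO")))
  }
  mf <- stats::model.frame(formula, data, na.action = NULL)
  for (j in seq_along(mf)) {
    v <- mf[[j]]
    if (is.numeric(v) && any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1]
      stop("non-finite value in term '", names(mf)[j], "' at row ", bad,
           " (log of a nonpositive value?)")
    }
  }
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X)
  if (n <= ncol(X))
    stop("need more observations (", n, ") than coefficients (", ncol(X),
         ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(formula, data = data)
  ## noiseless designs trip summary.lm's "essentially perfect fit" warning;
  ## exact recovery is a supported use, so keep the output quiet
  sm <- suppressWarnings(summary(fit))$coefficients
  y <- stats::model.response(mf)
  structure(list(
    coefTable = data.frame(term = rownames(sm), estimate = sm[, 1],
                           std_error = sm[, 2], t_value = sm[, 3],
                           p_value = sm[, 4], row.names = NULL),
    rSquared = rSquaredKvalseth(y, stats::fitted(fit)),
    fitted = stats::fitted(fit), residuals = stats::residuals(fit),
    lm = fit, formula = formula, data = data), class = "linearFit")
}

#' @export
print.linearFit <- function(x, ...) {
  cat("Linear model:", deparse(x$formula), "\n")
  print(x$coefTable, row.names = FALSE, digits = 5)
  cat("R-squared (Kvalseth):", round(x$rSquared, 4), "\n")
  invisible(x)
}

## R-squared of an OLS fit on an intercept plus the design columns in
## `cols`; cols may be empty (null model, R-squared 0).
subsetR2 <- function(y, X, cols) {
  if (!length(cols)) return(0)
  Xs <- cbind(1, X[, cols, drop = FALSE])
  fit <- stats::lm.fit(Xs, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Relative importance of predictors by averaging over orderings (lmg)
#'
#' Decomposes the model R-squared into one nonnegative-summing share per
#' model term: each term's share is its incremental R-squared averaged over
#' all `p!` orderings of the terms. Computed by subset enumeration with the
#' combinatorial ordering weights `|S|! (p - |S| - 1)! / p!`, which is
#' algebraically identical to the explicit average over orderings. Shares
#' always sum to the full-model R-squared; a factor term (e.g. `group`)
#' enters as one block.
#'
#' @param fit a `"linearFit"`.
#' @return Named numeric vector of shares, one per term, summing to the
#'   full-model R-squared.
#' @export
relativeImportanceLMG <- function(fit) {
  stopifnot(inherits(fit, "linearFit"))
  tl <- attr(stats::terms(fit$lm), "term.labels")
  p <- length(tl)
  if (p < 1) stop("model has no predictors")
  if (p > 8)
    stop("lmg by exact enumeration supports at most 8 terms; ",
         "sampling of orderings is not implemented")
  X <- stats::model.matrix(fit$lm)
  asg <- attr(X, "assign")
  y <- stats::model.response(stats::model.frame(fit$lm))
  colsOf <- lapply(seq_len(p), function(j) which(asg == j))
  ## cache R2 for every subset of terms
  r2 <- numeric(2^p)
  for (s in 0:(2^p - 1)) {
    terms <- which(bitwAnd(s, 2^(seq_len(p) - 1)) > 0)
    r2[s + 1] <- subsetR2(y, X, unlist(colsOf[terms]))
  }
  shares <- stats::setNames(numeric(p), tl)
  for (j in seq_len(p)) {
    bitJ <- 2^(j - 1)
    for (s in 0:(2^p - 1)) {
      if (bitwAnd(s, bitJ) > 0) next
      sz <- sum(bitwAnd(s, 2^(seq_len(p) - 1)) > 0)
      w <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
      shares[j] <- shares[j] + w * (r2[s + bitJ + 1] - r2[s + 1])
    }
  }
  shares
}

#' k-fold cross-validated predictions of a linear model
#'
#' Randomly assigns rows to `k` folds (seeded), and for each fold fits the
#' model on the remaining rows and predicts the held-out fold. A fold whose
#' training design is rank deficient (e.g. a factor level absent) is an
#' error naming the fold.
#'
#' @param formula model formula as in [fitLinear()].
#' @param data data frame.
#' @param k number of folds (default 3).
#' @param seed fold-assignment seed.
#' @return Data frame with `row`, `observed`, `predicted`, `fold`.
#' @export
kfoldPredictions <- function(formula, data, k = 3, seed = 1L) {
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n < k) stop("need at least k rows")
  if ("group" %in% names(data))
    data$group <- factor(as.character(data$group))
  folds <- withSeed(seed, sample(rep_len(seq_len(k), n)))
  mf <- stats::model.frame(formula, data, na.action = NULL)
  observed <- stats::model.response(mf)
  predicted <- numeric(n)
  for (fold in seq_len(k)) {
    hold <- folds == fold
    fit <- stats::lm(formula, data = data[!hold, , drop = FALSE])
    if (anyNA(stats::coef(fit)))
      stop("training design for fold ", fold, " is rank deficient")
    predicted[hold] <- stats::predict(fit,
                                      newdata = data[hold, , drop = FALSE])
  }
  data.frame(row = seq_len(n), observed = observed, predicted = predicted,
             fold = folds)
}
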