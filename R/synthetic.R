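## Synthetic data generators: seeded micrographs with ground-truth masks and
## tabular datasets carrying the statistical structure the analysis assumes.

#' Parameters for a synthetic micrograph
#'
#' Describes a four-class hematoxylin--eosin-like micrograph: target area
#' fractions, per-class mean colour, colour noise and texture grain
#' length-scale. Classes follow the fixed label encoding
#' (0 = background, 1 = collagen, 2 = extracellular matrix, 3 = nuclei);
#' `classFractions`, `colors`, `noiseSd` and `grainScale` are all indexed in
#' that order.
#'
#' Default colours mimic an H&E stain: near-white background, eosin-pink
#' collagen, violet extracellular matrix and dark basophilic nuclei. Collagen
#' and matrix are given closely matched luma but different hue and grain so
#' that they are separable by texture, not by a single grayscale threshold.
#'
#' @param width,height image size in pixels (at least 64).
#' @param classFractions numeric length-4 vector of target area fractions in
#'   label order, nonnegative, summing to 1 (tolerance 1e-9).
#' @param colors 4 x 3 matrix of per-class mean RGB (0--255), label order.
#' @param noiseSd per-class colour noise standard deviation (0--255 scale).
#' @param grainScale per-class texture grain length-scale in pixels (Gaussian
#'   smoothing sigma applied to the colour noise).
#' @param regionScale length-scale (px) of the random field whose level bands
#'   form the background/collagen/matrix regions.
#' @param nucleiRadius mean nucleus radius in pixels.
#' @param pixelSize physical pixel size in um/px.
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return A validated list of class `"syntheticImageParams"`.
#' @export
syntheticImageParams <- function(width = 128, height = 128,
    classFractions = c(0.25, 0.40, 0.25, 0.10),
    colors = rbind(background = c(240, 235, 242),
                   collagen   = c(200, 150, 185),
                   matrix     = c(170, 160, 200),
                   nuclei     = c(60, 50, 110)),
    noiseSd = c(5, 9, 13, 6),
    grainScale = c(1.5, 1.5, 4, 1.5),
    regionScale = 10,
    nucleiRadius = 3,
    pixelSize = 300 / 189,
    seed = 1L) {
  if (width < 64 || height < 64)
    stop("width and height must be at least 64 px")
  if (length(classFractions) != 4L || any(classFractions < 0) ||
      abs(sum(classFractions) - 1) > 1e-9)
    stop("classFractions must be 4 nonnegative values summing to 1")
  colors <- as.matrix(colors)
  if (!all(dim(colors) == c(4L, 3L)) || any(colors < 0) || any(colors > 255))
    stop("colors must be a 4 x 3 matrix of RGB values in [0, 255]")
  if (length(noiseSd) != 4L || any(noiseSd < 0))
    stop("noiseSd must be 4 nonnegative values")
  if (length(grainScale) != 4L || any(grainScale <= 0))
    stop("grainScale must be 4 positive length-scales")
  if (nucleiRadius < 1) stop("nucleiRadius must be >= 1 px")
  structure(list(width = as.integer(width), height = as.integer(height),
                 classFractions = as.numeric(classFractions),
                 colors = round(colors), noiseSd = as.numeric(noiseSd),
                 grainScale = as.numeric(grainScale),
                 regionScale = regionScale, nucleiRadius = nucleiRadius,
                 pixelSize = pixelSize, seed = as.integer(seed)),
            class = "syntheticImageParams")
}

## Correlated standard-normal field: smoothed white noise rescaled to unit sd.
correlatedField <- function(nr, nc, scale) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  s <- convSeparable(z, gaussKernel(scale))
  (s - mean(s)) / stats::sd(s)
}

## Stamp quasi-elliptical nuclei onto `mask` until `target` pixels carry
## label 3 (or maxBlobs is reached). Nuclei sit on top of tissue.
stampNuclei <- function(mask, target, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  count <- sum(mask == 3L)
  maxBlobs <- ceiling(4 * target / (pi * radius^2)) + 50L
  tries <- 0L
  while (count < target && tries < maxBlobs) {
    tries <- tries + 1L
    cy <- stats::runif(1, 1, nr); cx <- stats::runif(1, 1, nc)
    a <- radius * stats::runif(1, 0.85, 1.25)          # semi-major
    b <- a * stats::runif(1, 0.6, 1)                   # semi-minor
    th <- stats::runif(1, 0, pi)
    yr <- max(1L, floor(cy - a - 1)):min(nr, ceiling(cy + a + 1))
    xr <- max(1L, floor(cx - a - 1)):min(nc, ceiling(cx + a + 1))
    yy <- outer(yr - cy, rep(1, length(xr)))
    xx <- outer(rep(1, length(yr)), xr - cx)
    u <- cos(th) * xx + sin(th) * yy
    v <- -sin(th) * xx + cos(th) * yy
    inside <- (u / a)^2 + (v / b)^2 <= 1
    sub <- mask[yr, xr, drop = FALSE]
    sub[inside] <- 3L
    mask[yr, xr] <- sub
    count <- sum(mask == 3L)
  }
  mask
}

#' Generate a synthetic micrograph with its ground-truth label mask
#'
#' Builds a four-region image whose label regions partition every pixel:
#' background, collagen and extracellular-matrix regions are level bands of a
#' smooth random field (cut at quantiles so realized area fractions track the
#' targets), and nuclei are quasi-elliptical blobs stamped on top. Each class
#' is textured as its mean colour plus seeded correlated noise at the class's
#' grain length-scale, so classes differ in texture and not only in colour.
#' Pixels are quantized to 8-bit; the same parameters and seed give
#' bit-identical output.
#'
#' @param params a [syntheticImageParams()] object.
#' @return A list with elements `micrograph` (a [Micrograph-class]) and
#'   `mask` (integer matrix of labels 0--3, same height/width).
#' @examples
#' p <- syntheticImageParams(width = 64, height = 64, seed = 7)
#' g <- generateMicrograph(p)
#' table(g$mask) / (64 * 64)
#' @export
generateMicrograph <- function(params) {
  if (!inherits(params, "syntheticImageParams"))
    params <- do.call(syntheticImageParams, params)
  withSeed(params$seed, {
    nr <- params$height; nc <- params$width
    npix <- nr * nc
    f <- params$classFractions

    ## nuclei first (stamped on top of tissue; ties favour nuclei)
    mask <- matrix(-1L, nr, nc)
    targetNuc <- round(f[4] * npix)
    if (targetNuc > 0)
      mask <- stampNuclei(mask, targetNuc, params$nucleiRadius)

    ## remaining pixels: band a correlated field at renormalized quantiles
    free <- mask != 3L
    field <- correlatedField(nr, nc, params$regionScale)
    fv <- field[free]
    f3 <- f[1:3]
    if (sum(f3) <= 0) f3 <- c(1, 0, 0) else f3 <- f3 / sum(f3)
    ## band order along the field: collagen low, matrix mid, background high
    ## (arbitrary but fixed); cut points at renormalized quantiles.
    q1 <- stats::quantile(fv, f3[2], names = FALSE)
    q2 <- stats::quantile(fv, f3[2] + f3[3], names = FALSE)
    lab <- ifelse(fv <= q1, 1L, ifelse(fv <= q2, 2L, 0L))
    mask[free] <- lab

    ## texture each class
    img <- array(0, dim = c(nr, nc, 3))
    for (cls in 0:3) {
      sel <- mask == cls
      if (!any(sel)) next
      base <- params$colors[cls + 1L, ]
      sdc <- params$noiseSd[cls + 1L]
      if (sdc > 0) {
        for (ch in 1:3) {
          noise <- correlatedField(nr, nc, params$grainScale[cls + 1L])
          plane <- img[, , ch]
          plane[sel] <- base[ch] + sdc * noise[sel]
          img[, , ch] <- plane
        }
      } else {
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[sel] <- base[ch]
          img[, , ch] <- plane
        }
      }
    }
    img <- pmin(pmax(round(img), 0), 255)
    list(micrograph = Micrograph(img, pixelSize = params$pixelSize),
         mask = mask)
  })
}

#' Generate a time series of synthetic micrographs
#'
#' Emulates a 0--44-day culture series in which the extracellular-matrix area
#' fraction grows while the collagen fraction shrinks. The composition trend
#' is validated (matrix nondecreasing, collagen nonincreasing, every row a
#' valid fraction vector) before any image is generated.
#'
#' @param times strictly increasing numeric vector of days in `[0, 44]`.
#' @param fractions numeric matrix `length(times) x 4` of class fractions in
#'   label order (background, collagen, matrix, nuclei).
#' @param template a [syntheticImageParams()] giving size, colours and
#'   texture for every frame.
#' @param seed integer seed; per-frame seeds are derived deterministically.
#' @return A list of `length(times)` elements, each with `micrograph`,
#'   `mask` and `time`.
#' @export
generateSeries <- function(times, fractions, template = syntheticImageParams(),
                           seed = 1L) {
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (min(times) < 0 || max(times) > 44)
    stop("times must lie in [0, 44] days")
  fractions <- as.matrix(fractions)
  if (nrow(fractions) != length(times) || ncol(fractions) != 4L)
    stop("fractions must be a length(times) x 4 matrix")
  if (any(fractions < 0) || any(abs(rowSums(fractions) - 1) > 1e-9))
    stop("every row of fractions must be nonnegative and sum to 1")
  if (any(diff(fractions[, 3]) < -1e-12))
    stop("extracellular-matrix fraction must be nondecreasing over time")
  if (any(diff(fractions[, 2]) > 1e-12))
    stop("collagen fraction must be nonincreasing over time")
  lapply(seq_along(times), function(i) {
    p <- template
    p$classFractions <- fractions[i, ]
    p$seed <- as.integer(seed + 7919L * i) %% .Machine$integer.max
    g <- generateMicrograph(p)
    g$micrograph@time <- times[i]
    list(micrograph = g$micrograph, mask = g$mask, time = times[i])
  })
}

#' Simulate mass-loss records from a logistic mixture
#'
#' Draws mass-loss percentages at the given times as the logistic-mixture mean
#' plus independent Gaussian noise. With `noiseSd = 0` the records lie exactly
#' on the mixture curve.
#'
#' @param theta numeric vector of length `3k`:
#'   `(A1, mu1, scal1, ..., Ak, muk, scalk)` with `A_i > 0`, `scal_i > 0`.
#' @param times numeric vector of observation days.
#' @param noiseSd Gaussian noise standard deviation in mass-loss percentage
#'   points.
#' @param group optional group label stored in the output.
#' @param seed integer seed.
#' @return A data frame with columns `time_days`, `group`, `mass_loss_pct`.
#' @examples
#' simulateMassLoss(c(10, 5, 1), times = 5, noiseSd = 0)  # A/2 = 5 at t = mu
#' @export
simulateMassLoss <- function(theta, times, noiseSd = 0, group = NA_character_,
                             seed = 1L) {
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  mu <- mixturePredict(times, theta)
  y <- withSeed(seed, mu + stats::rnorm(length(times), 0, noiseSd))
  data.frame(time_days = as.numeric(times), group = group,
             mass_loss_pct = y)
}

#' Simulate a per-image feature table on the multivariate log-linear model
#'
#' Generates rows for the three experimental groups (CCO as reference, CCT and
#' CO as 0/1 dummies) with positive feature draws, and computes mass loss as
#' the linear predictor on log-transformed features plus Gaussian noise:
#' `intercept + bCCT*CCT + bCO*CO + bLnCirc*ln(circ) + bLnMode*ln(mode) +
#' bLnArea*ln(area) + e`.
#'
#' @param coefficients named numeric vector with elements `intercept`, `CCT`,
#'   `CO`, `lnCircularity`, `lnMode`, `lnArea`.
#' @param nPerGroup rows per group.
#' @param ranges list with strictly positive ranges `circularity`, `mode`,
#'   `area` (each `c(lo, hi)`) from which predictors are drawn uniformly.
#' @param noiseSd Gaussian noise sd in mass-loss percentage points.
#' @param seed integer seed.
#' @return Data frame with columns `group`, `mean_circularity`, `gray_mode`,
#'   `mean_area_um2`, `mass_loss_pct`.
#' @export
simulateFeatureTable <- function(coefficients, nPerGroup = 20,
    ranges = list(circularity = c(0.02, 0.9), mode = c(60, 240),
                  area = c(50, 5000)),
    noiseSd = 0, seed = 1L) {
  need <- c("intercept", "CCT", "CO", "lnCircularity", "lnMode", "lnArea")
  if (!all(need %in% names(coefficients)))
    stop("coefficients must be named: ", paste(need, collapse = ", "))
  for (nm in c("circularity", "mode", "area")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2L || any(r <= 0) || r[1] >= r[2])
      stop("ranges$", nm, " must be a strictly positive (lo, hi) interval")
  }
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  withSeed(seed, {
    n <- 3L * nPerGroup
    grp <- rep(c("CCO", "CCT", "CO"), each = nPerGroup)
    circ <- stats::runif(n, ranges$circularity[1], ranges$circularity[2])
    mode <- stats::runif(n, ranges$mode[1], ranges$mode[2])
    area <- stats::runif(n, ranges$area[1], ranges$area[2])
    b <- coefficients
    y <- b[["intercept"]] + b[["CCT"]] * (grp == "CCT") +
      b[["CO"]] * (grp == "CO") + b[["lnCircularity"]] * log(circ) +
      b[["lnMode"]] * log(mode) + b[["lnArea"]] * log(area) +
      stats::rnorm(n, 0, noiseSd)
    data.frame(group = grp, mean_circularity = circ, gray_mode = mode,
               mean_area_um2 = area, mass_loss_pct = y)
  })
}
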