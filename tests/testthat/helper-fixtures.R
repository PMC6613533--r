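## Shared fixtures and independent brute-force oracles used across tests.
## Heavy objects (feature stacks, trained forests) are built once per run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

## The standard synthetic fixture: a 96 x 96 four-class micrograph at the
## generator defaults (collagen and matrix share luma but differ in hue and
## texture grain), its ground-truth mask, feature stack, training sample and
## fitted forest.
standardFixture <- function() {
  cached("standard", function() {
    g <- generateMicrograph(syntheticImageParams(width = 96, height = 96,
                                                 seed = 7))
    stack <- buildFeatureStack(g$micrograph)
    train <- sampleTrainingPixels(stack, g$mask, nPerClass = 150, seed = 1)
    model <- trainClassifier(train, nTrees = 150, seed = 1)
    list(micrograph = g$micrograph, mask = g$mask, stack = stack,
         train = train, model = model)
  })
}

## Noiseless fixture: constant colour per class, perfectly separable.
noiselessFixture <- function() {
  cached("noiseless", function() {
    g <- generateMicrograph(syntheticImageParams(width = 64, height = 64,
                                                 noiseSd = rep(0, 4),
                                                 seed = 3))
    stack <- buildFeatureStack(g$micrograph)
    train <- sampleTrainingPixels(stack, g$mask, nPerClass = 120, seed = 2)
    model <- trainClassifier(train, nTrees = 100, seed = 2)
    list(micrograph = g$micrograph, mask = g$mask, stack = stack,
         train = train, model = model)
  })
}

## Reflected (edge-repeating) index into 1..n.
reflIdx <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i,
                                                      i))

## Brute-force per-pixel structure-tensor eigendecomposition: explicit
## gradient loops, explicit Gaussian window sums, dense eigen() per pixel.
bruteTensorEigen <- function(ch, sigma) {
  nr <- nrow(ch); nc <- ncol(ch)
  k <- max(1, ceiling(3 * sigma))
  w <- exp(-((-k):k)^2 / (2 * sigma^2)); w <- w / sum(w)
  W <- outer(w, w)
  fx <- matrix(0, nr, nc); fy <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    fx[i, j] <- (ch[i, reflIdx(j + 1, nc)] - ch[i, reflIdx(j - 1, nc)]) / 2
    fy[i, j] <- (ch[reflIdx(i + 1, nr), j] - ch[reflIdx(i - 1, nr), j]) / 2
  }
  lmax <- matrix(0, nr, nc); lmin <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    jxx <- 0; jxy <- 0; jyy <- 0
    for (a in -k:k) for (b in -k:k) {
      ii <- reflIdx(i + a, nr); jj <- reflIdx(j + b, nc)
      wt <- W[a + k + 1, b + k + 1]
      jxx <- jxx + wt * fx[ii, jj]^2
      jxy <- jxy + wt * fx[ii, jj] * fy[ii, jj]
      jyy <- jyy + wt * fy[ii, jj]^2
    }
    ev <- eigen(matrix(c(jxx, jxy, jxy, jyy), 2, 2), symmetric = TRUE,
                only.values = TRUE)$values
    lmax[i, j] <- ev[1]; lmin[i, j] <- ev[2]
  }
  list(lambdaMax = lmax, lambdaMin = lmin)
}

## Brute-force per-pixel circular-neighbourhood entropy.
bruteEntropy <- function(ch, r, nBins = 256) {
  nr <- nrow(ch); nc <- ncol(ch)
  out <- matrix(0, nr, nc)
  bw <- 256 / nBins
  for (i in 1:nr) for (j in 1:nc) {
    vals <- c()
    for (a in -floor(r):floor(r)) for (b in -floor(r):floor(r))
      if (a^2 + b^2 <= r^2)
        vals <- c(vals, ch[reflIdx(i + a, nr), reflIdx(j + b, nc)])
    bins <- pmin(floor(vals / bw), nBins - 1)
    p <- table(bins) / length(bins)
    out[i, j] <- -sum(p * log2(p))
  }
  out
}

## Printed reference values used in worked examples: the published pixel
## confusion matrix (rows/columns: collagen, extracellular matrix, nuclei,
## background) and kinetic/regression parameter sets.
publishedConfusion <- function() {
  m <- rbind(c(5727, 220, 25, 10),
             c(92, 5630, 36, 16),
             c(7, 90, 1073, 4),
             c(1, 7, 9, 6361))
  dimnames(m) <- list(c("collagen", "matrix", "nuclei", "background"),
                      c("collagen", "matrix", "nuclei", "background"))
  m
}

thetaCCO <- c(50.223, 1.734, 1.000, 23.463, 16.261, 1.3233)
thetaCCT <- c(52.502, 2.4768, 1.1546, 21.653, 16.881, 3.6554)

multivarCoefs <- c(intercept = -17.0396, CCT = -0.215, CO = -2.1751,
                   lnCircularity = -0.0599, lnMode = 3.7804,
                   lnArea = 0.1760)
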