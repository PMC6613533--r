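## Per-pixel texture features: structure-tensor eigenvalues and local Shannon
## entropy, computed per colour channel in both RGB and HSB representations.

#' Structure-tensor eigenvalue maps of one channel
#'
#' Computes, at every pixel, the eigenvalues of the smoothed structure tensor
#' \deqn{J = \begin{pmatrix} \langle f_x, f_x\rangle_w & \langle f_x, f_y\rangle_w \\
#'                           \langle f_x, f_y\rangle_w & \langle f_y, f_y\rangle_w \end{pmatrix}}
#' where \eqn{f_x, f_y} are central-difference partial derivatives (reflect
#' boundary handling) and \eqn{\langle\cdot,\cdot\rangle_w} averages the
#' products under a Gaussian window of standard deviation `sigma`. Since `J`
#' is symmetric 2x2, eigenvalues come from the closed form
#' \eqn{\lambda = tr/2 \pm \sqrt{(tr/2)^2 - \det}}; positive semidefiniteness
#' of `J` guarantees both maps are nonnegative up to roundoff.
#'
#' Boundary pixels are computed under reflection rather than masked; treat
#' them as lower-confidence.
#'
#' @param channel numeric matrix (one image channel), finite values, at least
#'   3 x 3.
#' @param sigma Gaussian window standard deviation in pixels (default 2).
#' @return List with matrices `lambdaMax` and `lambdaMin`, same shape as the
#'   input.
#' @export
structureTensorEigen <- function(channel, sigma = 2) {
  if (!is.matrix(channel) || nrow(channel) < 3 || ncol(channel) < 3)
    stop("channel must be a matrix of size at least 3 x 3")
  if (!all(is.finite(channel)))
    stop("channel must be finite-valued")
  if (sigma <= 0) stop("sigma must be positive")
  g <- gradientCentral(channel)
  k <- gaussKernel(sigma)
  jxx <- convSeparable(g$fx * g$fx, k)
  jxy <- convSeparable(g$fx * g$fy, k)
  jyy <- convSeparable(g$fy * g$fy, k)
  tr2 <- (jxx + jyy) / 2
  disc <- sqrt(pmax(tr2^2 - (jxx * jyy - jxy^2), 0))
  list(lambdaMax = tr2 + disc, lambdaMin = tr2 - disc)
}

## Integer offsets of a circular neighbourhood of radius r (centre included).
circleOffsets <- function(r) {
  d <- (-floor(r)):floor(r)
  off <- expand.grid(dy = d, dx = d)
  off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
}

#' Local Shannon entropy map of one channel
#'
#' For each pixel, a circle of radius `r` is drawn around it, the intensity
#' histogram of the covered pixels is formed over `nBins` equal-width bins on
#' `[0, 255]`, and the Shannon entropy \eqn{-\sum_b p_b \log_2 p_b} of the
#' normalized histogram is returned (with `0 log 0 = 0`). Boundaries are
#' handled by reflection.
#'
#' @param channel numeric matrix with values in `[0, 255]`.
#' @param r neighbourhood radius in pixels (>= 1, and at most half the
#'   smaller image dimension).
#' @param nBins number of histogram bins (>= 2; default 256, i.e. one bin per
#'   8-bit level).
#' @return Matrix of entropies in bits, bounded by `log2(nBins)`.
#' @export
localEntropy <- function(channel, r = 4, nBins = 256) {
  if (!is.matrix(channel)) stop("channel must be a matrix")
  if (r < 1) stop("r must be >= 1")
  if (nBins < 2) stop("nBins must be >= 2")
  nr <- nrow(channel); nc <- ncol(channel)
  if (r > min(nr, nc) / 2)
    stop("entropy radius r exceeds half the smaller image dimension")
  if (min(channel) < 0 || max(channel) > 255)
    stop("channel intensities must lie within [0, 255]")
  bin <- pmin(floor(channel / (256 / nBins)), nBins - 1L) + 1L
  rInt <- floor(r)
  p <- padReflect(bin, rInt)
  off <- circleOffsets(r)
  npix <- nr * nc
  counts <- matrix(0L, npix, nBins)
  idx <- seq_len(npix)
  for (i in seq_len(nrow(off))) {
    sh <- p[off$dy[i] + rInt + seq_len(nr), off$dx[i] + rInt + seq_len(nc),
            drop = FALSE]
    j <- cbind(idx, as.vector(sh))
    counts[j] <- counts[j] + 1L
  }
  pr <- counts / nrow(off)
  h <- -rowSums(ifelse(pr > 0, pr * log2(pr), 0))
  matrix(h, nr, nc)
}

#' Texture feature stack of a micrograph
#'
#' Concatenates, for each of the six channels (R, G, B, then hue, saturation,
#' brightness scaled to 0--255), the raw intensity, the two structure-tensor
#' eigenvalue maps and the local-entropy map: 24 feature planes in the fixed
#' order `<channel>.intensity`, `<channel>.lambdaMax`, `<channel>.lambdaMin`,
#' `<channel>.entropy` for channels `R, G, B, H, S, V`. The order is part of
#' the public contract; trained models refuse stacks whose feature names do
#' not match.
#'
#' @param image a [Micrograph-class] (RGB; grayscale input is rejected).
#' @param sigma structure-tensor Gaussian window sd in pixels.
#' @param r entropy neighbourhood radius in pixels.
#' @param nBins entropy histogram bins.
#' @return A [FeatureStack-class] with `F = 24` planes (stored as
#'   single-precision-range reals).
#' @export
buildFeatureStack <- function(image, sigma = 2, r = 4, nBins = 256) {
  if (!is(image, "Micrograph")) {
    d <- dim(image)
    if (is.null(d) || length(d) != 3L || d[3] != 3L)
      stop("image must be a Micrograph or an RGB height x width x 3 array")
    image <- Micrograph(image)
  }
  px <- pixelData(image)
  hsb <- rgbToHsb255(px)
  chans <- list(R = px[, , 1], G = px[, , 2], B = px[, , 3],
                H = hsb$H, S = hsb$S, V = hsb$B)
  nr <- dim(px)[1]; nc <- dim(px)[2]
  feats <- array(0, dim = c(nr, nc, 4L * length(chans)))
  nms <- character(4L * length(chans))
  i <- 0L
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    ev <- structureTensorEigen(ch, sigma = sigma)
    en <- localEntropy(ch, r = r, nBins = nBins)
    feats[, , i + 1L] <- ch
    feats[, , i + 2L] <- ev$lambdaMax
    feats[, , i + 3L] <- ev$lambdaMin
    feats[, , i + 4L] <- en
    nms[i + 1:4] <- paste(nm, c("intensity", "lambdaMax", "lambdaMin",
                                "entropy"), sep = ".")
    i <- i + 4L
  }
  new("FeatureStack", features = feats, featureNames = nms)
}
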