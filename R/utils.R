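## Internal numeric helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's state afterwards so seeded generators behave as pure functions.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Reflect-pad a matrix by k rows/cols on every side (edge pixel repeated:
## c b a | a b c).
padReflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(k, nr))), seq_len(nr),
          nr + 1 - seq_len(min(k, nr)))
  if (k > nr) ri <- ri[seq_len(nr + 2 * k)]  # guarded by callers
  ci <- c(rev(seq_len(min(k, nc))), seq_len(nc),
          nc + 1 - seq_len(min(k, nc)))
  m[ri, ci, drop = FALSE]
}

## Separable convolution of matrix m with a 1-D kernel along rows then
## columns, reflect boundary handling. Kernel length must be odd.
convSeparable <- function(m, kernel) {
  k <- (length(kernel) - 1L) %/% 2L
  if (k == 0L) return(m * kernel)
  p <- padReflect(m, k)
  nr <- nrow(m); nc <- ncol(m)
  ## along columns (vertical)
  tmp <- matrix(0, nr, nc + 2L * k)
  for (i in seq_along(kernel))
    tmp <- tmp + kernel[i] * p[(i - 1L) + seq_len(nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(kernel))
    out <- out + kernel[i] * tmp[, (i - 1L) + seq_len(nc), drop = FALSE]
  out
}

## Normalised Gaussian kernel, truncated at 3 sigma (minimum half-width 1).
gaussKernel <- function(sigma) {
  k <- max(1L, ceiling(3 * sigma))
  x <- (-k):k
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

## Central-difference gradients with reflect boundaries. x runs along
## columns, y along rows. Unit pixel spacing.
gradientCentral <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  cl <- c(1L, seq_len(nc - 1L)); cr <- c(seq_len(nc - 1L) + 1L, nc)
  rt <- c(1L, seq_len(nr - 1L)); rb <- c(seq_len(nr - 1L) + 1L, nr)
  list(
    fx = (m[, cr, drop = FALSE] - m[, cl, drop = FALSE]) / 2,
    fy = (m[rb, , drop = FALSE] - m[rt, , drop = FALSE]) / 2
  )
}

## 8-bit luma (Rec. 601 weights), rounded to integers in 0..255.
lumaGray <- function(pixels) {
  g <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  pmin(pmax(round(g), 0), 255)
}

## RGB (0..255) -> HSB planes scaled to 0..255. Hue's circular topology is
## ignored downstream (documented limitation).
rgbToHsb255 <- function(pixels) {
  d <- dim(pixels)
  rgb <- rbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
               as.vector(pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  list(
    H = matrix(hsv[1, ] * 255, d[1], d[2]),
    S = matrix(hsv[2, ] * 255, d[1], d[2]),
    B = matrix(hsv[3, ] * 255, d[1], d[2])
  )
}

## Validate a label mask: integer matrix with values 0..3.
checkLabelMask <- function(mask, what = "mask") {
  if (!is.matrix(mask))
    stop(what, " must be a matrix", call. = FALSE)
  if (anyNA(mask) || !all(mask %in% 0:3))
    stop(what, " must contain only labels 0, 1, 2, 3", call. = FALSE)
  invisible(TRUE)
}
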