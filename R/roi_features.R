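## Object-level shape features of segmented regions: connected components,
## area, contour perimeter, circularity, equivalent-ellipse axes, and the
## grayscale histogram mode.

## 8-connected labelling: EBImage::bwlabel (4-connected) followed by a
## union-find merge of diagonally touching components.
labelComponents8 <- function(bin) {
  lab <- EBImage::imageData(EBImage::bwlabel(bin))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      a <- findRoot(pairs[i, 1]); b <- findRoot(pairs[i, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

## Closed-polygon length of each object's oriented contour.
contourPerimeters <- function(lab, nObjects) {
  oc <- EBImage::ocontour(lab)
  per <- numeric(nObjects)
  for (nm in names(oc)) {
    pts <- oc[[nm]]
    id <- as.integer(nm)
    if (is.na(id) || id < 1 || id > nObjects) next
    if (nrow(pts) < 2) { per[id] <- per[id] + 0; next }
    d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
    per[id] <- per[id] + sum(d)
  }
  per
}

#' Extract per-object shape features from a binary region mask
#'
#' Labels 8-connected components of at least `minSizePx` pixels and computes,
#' per object: pixel and physical area, contour perimeter (polygon length of
#' the traced boundary), circularity `min(1, 4*pi*area/perimeter^2)`
#' (capped at 1 because digital perimeters otherwise exceed it for small
#' objects), equivalent-ellipse axes from second central moments
#' (`axis = 4*sqrt(eigenvalue)` of the pixel-coordinate covariance with the
#' 1/12 unit-pixel correction), and roundness `4*area/(pi*major^2)`.
#'
#' @param binaryMask logical or 0/1 matrix marking the region of interest.
#' @param pixelScaleUm physical pixel size in um/px (default `300/189`, the
#'   package's microscope calibration).
#' @param minSizePx despeckle filter: components smaller than this are
#'   dropped (default 10).
#' @return Data frame with one row per object and columns `object_id`,
#'   `area_px`, `area_um2`, `perimeter_px`, `circularity`,
#'   `ellipse_major_px`, `ellipse_minor_px`, `roundness`. An empty mask
#'   yields an empty data frame.
#' @export
extractObjects <- function(binaryMask, pixelScaleUm = 300 / 189,
                           minSizePx = 10) {
  if (pixelScaleUm <= 0) stop("pixelScaleUm must be positive")
  bin <- matrix(as.integer(binaryMask != 0), nrow(binaryMask),
                ncol(binaryMask))
  empty <- data.frame(object_id = integer(0), area_px = numeric(0),
                      area_um2 = numeric(0), perimeter_px = numeric(0),
                      circularity = numeric(0), ellipse_major_px = numeric(0),
                      ellipse_minor_px = numeric(0), roundness = numeric(0))
  if (!any(bin > 0)) return(empty)
  lab <- labelComponents8(bin)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= minSizePx)
  if (!length(keep)) return(empty)
  ## drop small components and relabel consecutively
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  nObj <- length(keep)
  per <- contourPerimeters(lab, nObj)
  rows <- lapply(seq_len(nObj), function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    a <- nrow(idx)
    ## second central moments with the unit-pixel (1/12) correction
    myy <- stats::var(idx[, 1]) * (a - 1) / a + 1 / 12
    mxx <- stats::var(idx[, 2]) * (a - 1) / a + 1 / 12
    mxy <- if (a > 1)
      stats::cov(idx[, 1], idx[, 2]) * (a - 1) / a else 0
    ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2),
                symmetric = TRUE, only.values = TRUE)$values
    major <- 4 * sqrt(max(ev[1], 0))
    minor <- 4 * sqrt(max(ev[2], 0))
    p <- per[id]
    circ <- if (p > 0) min(1, 4 * pi * a / p^2) else 1
    data.frame(object_id = id, area_px = a,
               area_um2 = a * pixelScaleUm^2, perimeter_px = p,
               circularity = circ, ellipse_major_px = major,
               ellipse_minor_px = minor,
               roundness = if (major > 0) min(1, 4 * a / (pi * major^2))
                 else 1)
  })
  do.call(rbind, rows)
}

#' Grayscale histogram mode of a region
#'
#' The most frequent 8-bit luma value among the masked pixels; ties are
#' resolved toward the lowest intensity.
#'
#' @param image a [Micrograph-class] or RGB array.
#' @param roiMask logical or 0/1 matrix selecting the region; must select at
#'   least one pixel.
#' @return Integer in `[0, 255]`.
#' @export
grayscaleMode <- function(image, roiMask) {
  px <- if (is(image, "Micrograph")) pixelData(image) else image
  sel <- roiMask != 0
  if (!any(sel)) stop("roiMask selects no pixels")
  g <- lumaGray(px)[sel]
  counts <- tabulate(g + 1L, nbins = 256L)
  as.integer(which.max(counts) - 1L)
}

#' Summarize one image's region of interest
#'
#' Aggregates an object table into the per-image record used by the
#' statistical models: number of objects, mean physical area, mean
#' circularity and the grayscale histogram mode of the region. Images with no
#' surviving objects get `NA` means and `n_objects = 0`.
#'
#' @param objects object table from [extractObjects()].
#' @param image the source [Micrograph-class].
#' @param roiMask logical or 0/1 matrix of the region of interest.
#' @param time acquisition day (defaults to the micrograph's).
#' @param group group label (defaults to the micrograph's).
#' @return One-row data frame with `time_days`, `group`, `n_objects`,
#'   `mean_area_um2`, `mean_circularity`, `gray_mode`.
#' @export
summarizeImage <- function(objects, image, roiMask, time = NULL,
                           group = NULL) {
  if (is.null(time))
    time <- if (is(image, "Micrograph")) timeDays(image) else NA_real_
  if (is.null(group))
    group <- if (is(image, "Micrograph")) groupLabel(image) else NA_character_
  n <- nrow(objects)
  mode <- if (any(roiMask != 0)) grayscaleMode(image, roiMask) else NA_integer_
  data.frame(time_days = time, group = group, n_objects = n,
             mean_area_um2 = if (n) mean(objects$area_um2) else NA_real_,
             mean_circularity = if (n) mean(objects$circularity)
               else NA_real_,
             gray_mode = mode)
}
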