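## Disk interfaces: images, masks, feature stacks, fitted models.

#' Write a micrograph or label mask to disk
#'
#' Micrographs are written as 8-bit RGB PNG/TIFF; label masks as
#' single-channel images whose pixel values encode the labels 0--3 directly
#' (stored as value/255 so readers recover the integer label by rescaling).
#'
#' @param x a [Micrograph-class] or an integer label matrix.
#' @param path output file; the extension picks the format (png or tiff).
#' @return `path`, invisibly.
#' @export
writeMicrograph <- function(x, path) {
  if (is(x, "Micrograph")) {
    px <- pixelData(x) / 255
    img <- EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color")
  } else {
    checkLabelMask(x)
    img <- EBImage::Image(t(x) / 255)
  }
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Read a micrograph from disk
#'
#' @param path PNG/TIFF file with an 8-bit RGB image.
#' @param pixelSize,time,group metadata attached to the result.
#' @return A [Micrograph-class].
#' @export
readMicrograph <- function(path, pixelSize = 300 / 189, time = NA_real_,
                           group = NA_character_) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L)
    stop("grayscale image: an RGB micrograph is required")
  a <- a[, , 1:3, drop = FALSE]
  px <- aperm(a, c(2, 1, 3)) * 255
  Micrograph(round(px), pixelSize = pixelSize, time = time, group = group)
}

#' Export a feature stack as a multi-page TIFF with a JSON sidecar
#'
#' Each feature plane is min-max scaled to `[0, 1]` for storage; the sidecar
#' records the plane names and the (offset, scale) pairs needed to undo the
#' scaling.
#'
#' @param stack a [FeatureStack-class].
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeFeatureStack <- function(stack, path) {
  fa <- featureArray(stack)
  nF <- dim(fa)[3]
  lo <- apply(fa, 3, min); hi <- apply(fa, 3, max)
  scaled <- array(0, dim(fa))
  for (i in seq_len(nF)) {
    rng <- hi[i] - lo[i]
    scaled[, , i] <- if (rng > 0) (fa[, , i] - lo[i]) / rng else 0
  }
  EBImage::writeImage(EBImage::Image(aperm(scaled, c(2, 1, 3))), path)
  jsonlite::write_json(list(featureNames = featureNames(stack),
                            offset = lo, scale = pmax(hi - lo, 0)),
                       paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Persist / restore a segmentation model
#'
#' The fitted forest is serialized to an RDS file and a JSON manifest beside
#' it records the feature-name contract and forest configuration, so
#' compatibility can be checked without deserializing.
#'
#' @param model a [SegmentationModel-class].
#' @param path output `.rds` path; manifest written at `<path>.json`.
#' @return `path` (write) or the restored model (read).
#' @export
saveSegmentationModel <- function(model, path) {
  stopifnot(is(model, "SegmentationModel"))
  saveRDS(model, path)
  jsonlite::write_json(list(featureNames = featureNames(model),
                            config = model@config,
                            package = "ScaffoldQuant"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveSegmentationModel
#' @export
loadSegmentationModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "SegmentationModel"))
  model
}
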