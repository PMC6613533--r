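#' @import methods
NULL

#' Micrograph: an RGB micrograph with acquisition metadata
#'
#' Container for a single hematoxylin--eosin-like micrograph. Pixel values are
#' stored as an 8-bit-range numeric array (`height x width x 3`, values in
#' `[0, 255]`) together with the physical pixel scale, the acquisition time
#' point and the experimental group label.
#'
#' @slot pixels numeric array `height x width x 3`, values in `[0, 255]`.
#' @slot pixelSize physical size of one pixel in micrometres. The default
#'   calibration used throughout the package is `300/189` um/px.
#' @slot time acquisition time in days (`NA` when unknown).
#' @slot group experimental group label, one of `"CCO"`, `"CCT"`, `"CO"`, or
#'   `NA` when unknown.
#'
#' @seealso [generateMicrograph()], [buildFeatureStack()]
#' @export
setClass("Micrograph",
  representation(
    pixels = "array",
    pixelSize = "numeric",
    time = "numeric",
    group = "character"
  ),
  prototype(
    pixelSize = 300 / 189,
    time = NA_real_,
    group = NA_character_
  )
)

setValidity("Micrograph", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be a height x width x 3 array")
  if (!all(is.finite(object@pixels)))
    return("pixels must be finite")
  if (min(object@pixels) < 0 || max(object@pixels) > 255)
    return("pixel values must lie in [0, 255]")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  TRUE
})

#' Construct a Micrograph
#'
#' @param pixels numeric array `height x width x 3` with values in `[0, 255]`.
#' @param pixelSize physical pixel size in micrometres per pixel.
#' @param time acquisition time in days.
#' @param group experimental group label (`"CCO"`, `"CCT"` or `"CO"`).
#' @return A [Micrograph-class] object.
#' @export
Micrograph <- function(pixels, pixelSize = 300 / 189, time = NA_real_,
                       group = NA_character_) {
  new("Micrograph", pixels = pixels, pixelSize = as.numeric(pixelSize),
      time = as.numeric(time), group = as.character(group))
}

#' FeatureStack: per-pixel texture feature planes
#'
#' Holds the per-pixel feature array used by the pixel classifier: for each of
#' the six colour channels (R, G, B, H, S, B) the raw intensity, the two
#' structure-tensor eigenvalues and the local entropy, in a fixed documented
#' order (24 planes).
#'
#' @slot features numeric array `height x width x F`.
#' @slot featureNames character vector of length `F` naming each plane; the
#'   order is part of the public contract and is checked when a trained model
#'   is applied to a stack.
#' @export
setClass("FeatureStack",
  representation(features = "array", featureNames = "character")
)

setValidity("FeatureStack", function(object) {
  d <- dim(object@features)
  if (length(d) != 3L)
    return("features must be a height x width x F array")
  if (d[3] != length(object@featureNames))
    return("length(featureNames) must equal the number of feature planes")
  TRUE
})

#' ProbabilityMaps: per-class pixel membership probabilities
#'
#' @slot maps numeric array `height x width x 4`; at each pixel the four class
#'   probabilities (background, collagen, extracellular matrix, nuclei in label
#'   order 0--3) are in `[0, 1]` and sum to 1.
#' @export
setClass("ProbabilityMaps", representation(maps = "array"))

setValidity("ProbabilityMaps", function(object) {
  d <- dim(object@maps)
  if (length(d) != 3L || d[3] != 4L)
    return("maps must be a height x width x 4 array")
  if (min(object@maps) < -1e-9 || max(object@maps) > 1 + 1e-9)
    return("probabilities must lie in [0, 1]")
  s <- apply(object@maps, c(1, 2), sum)
  if (max(abs(s - 1)) > 1e-6)
    return("per-pixel probabilities must sum to 1")
  TRUE
})

#' SegmentationModel: a fitted random-forest pixel classifier
#'
#' Wraps the fitted ensemble together with the feature-name contract and the
#' training configuration so that models can only be applied to compatible
#' feature stacks.
#'
#' @slot forest the fitted [ranger::ranger] probability forest.
#' @slot featureNames feature names seen at training time, in order.
#' @slot config list with the forest configuration (`nTrees`, `mtry`,
#'   `maxDepth`, `seed`).
#' @export
setClass("SegmentationModel",
  representation(forest = "ANY", featureNames = "character", config = "list")
)

## ---- accessors -----------------------------------------------------------

#' @describeIn Micrograph Pixel array accessor.
#' @param x object.
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname Micrograph-class
#' @export
setMethod("pixelData", "Micrograph", function(x) x@pixels)

#' @describeIn Micrograph Physical pixel size (um/px).
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname Micrograph-class
#' @export
setMethod("pixelSize", "Micrograph", function(x) x@pixelSize)

#' @describeIn Micrograph Acquisition time in days.
#' @export
setGeneric("timeDays", function(x) standardGeneric("timeDays"))

#' @rdname Micrograph-class
#' @export
setMethod("timeDays", "Micrograph", function(x) x@time)

#' @describeIn Micrograph Experimental group label.
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname Micrograph-class
#' @export
setMethod("groupLabel", "Micrograph", function(x) x@group)

#' Feature names of a stack or model
#' @param x a [FeatureStack-class] or [SegmentationModel-class].
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname FeatureStack-class
#' @export
setMethod("featureNames", "FeatureStack", function(x) x@featureNames)

#' @rdname SegmentationModel-class
#' @export
setMethod("featureNames", "SegmentationModel", function(x) x@featureNames)

#' Feature array accessor
#' @param x a [FeatureStack-class].
#' @export
setGeneric("featureArray", function(x) standardGeneric("featureArray"))

#' @rdname FeatureStack-class
#' @export
setMethod("featureArray", "FeatureStack", function(x) x@features)

#' Probability array accessor
#' @param x a [ProbabilityMaps-class].
#' @export
setGeneric("probMaps", function(x) standardGeneric("probMaps"))

#' @rdname ProbabilityMaps-class
#' @export
setMethod("probMaps", "ProbabilityMaps", function(x) x@maps)

## ---- show methods --------------------------------------------------------

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@pixels)
  cat("Micrograph: ", d[1], " x ", d[2], " px RGB\n", sep = "")
  cat("  pixel size: ", signif(object@pixelSize, 5), " um/px\n", sep = "")
  cat("  time: ", object@time, " days; group: ", object@group, "\n", sep = "")
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@features)
  cat("FeatureStack: ", d[1], " x ", d[2], " px, ", d[3], " features\n",
      sep = "")
  cat("  ", paste(utils::head(object@featureNames, 4), collapse = ", "),
      ", ...\n", sep = "")
})

setMethod("show", "ProbabilityMaps", function(object) {
  d <- dim(object@maps)
  cat("ProbabilityMaps: ", d[1], " x ", d[2], " px, 4 classes\n", sep = "")
})

setMethod("show", "SegmentationModel", function(object) {
  cat("SegmentationModel (random forest)\n")
  cat("  trees: ", object@config$nTrees, "; features: ",
      length(object@featureNames), "; seed: ", object@config$seed, "\n",
      sep = "")
})

## Region-of-interest label encoding shared by all modules:
## 0 = background, 1 = collagen, 2 = extracellular matrix, 3 = nuclei.

#' Region-of-interest class labels
#'
#' The fixed label encoding used by every module: 0 = background, 1 = type I
#' collagen, 2 = extracellular matrix, 3 = nuclei.
#'
#' @return Named integer vector of length 4.
#' @export
roiLabels <- function() {
  c(background = 0L, collagen = 1L, matrix = 2L, nuclei = 3L)
}
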