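## Random-forest pixel segmentation: training-pixel sampling, model fitting,
## probability maps, a grayscale-threshold baseline, and the validation
## metric suite (confusion matrix, per-class rates, cross-validation).

#' Sample a balanced training set of labelled pixels
#'
#' Draws up to `nPerClass` pixels per class, without replacement, from a
#' feature stack with a ground-truth label mask. Classes with fewer available
#' pixels are clamped to what exists (with a warning); in strict mode an
#' entirely missing class is an error.
#'
#' @param stack a [FeatureStack-class].
#' @param mask integer label matrix (0--3) of the same height/width.
#' @param nPerClass target pixels per class.
#' @param seed integer sampling seed.
#' @param strict if `TRUE` (default), error when a class has no pixels;
#'   otherwise missing classes are skipped.
#' @return An object of class `"trainingSet"`: list with `features`
#'   (n x F matrix, columns named), `labels` (integer vector 0--3), `coords`
#'   (n x 2 row/col), `featureNames`, `seed`.
#' @export
sampleTrainingPixels <- function(stack, mask, nPerClass = 200, seed = 1L,
                                 strict = TRUE) {
  stopifnot(is(stack, "FeatureStack"))
  checkLabelMask(mask)
  fa <- featureArray(stack)
  if (!all(dim(mask) == dim(fa)[1:2]))
    stop("mask and feature stack dimensions differ")
  present <- sort(unique(as.vector(mask)))
  missing <- setdiff(0:3, present)
  if (strict && length(missing))
    stop("mask is missing classes: ", paste(missing, collapse = ", "))
  withSeed(seed, {
    rows <- integer(0); labs <- integer(0)
    for (cls in present) {
      idx <- which(mask == cls)
      take <- min(nPerClass, length(idx))
      if (take < nPerClass)
        warning("class ", cls, ": only ", take, " pixels available")
      sel <- if (length(idx) == 1L) idx else sample(idx, take)
      rows <- c(rows, sel); labs <- c(labs, rep.int(cls, take))
    }
    npix <- prod(dim(fa)[1:2])
    fm <- matrix(fa, npix, dim(fa)[3])
    colnames(fm) <- featureNames(stack)
    structure(list(features = fm[rows, , drop = FALSE], labels = labs,
                   coords = cbind(row = ((rows - 1L) %% dim(fa)[1]) + 1L,
                                  col = ((rows - 1L) %/% dim(fa)[1]) + 1L),
                   featureNames = featureNames(stack), seed = seed),
              class = "trainingSet")
  })
}

#' Train the random-forest pixel classifier
#'
#' Fits a seeded probability forest to a labelled pixel sample. Class
#' probabilities are the fraction of tree votes. Defaults: 200 trees,
#' `sqrt(F)` candidate features per split, unbounded depth.
#'
#' @param train a `"trainingSet"` from [sampleTrainingPixels()].
#' @param nTrees number of trees (>= 1).
#' @param mtry candidate features per split; `NULL` means `floor(sqrt(F))`.
#' @param maxDepth maximal tree depth; 0 means unbounded.
#' @param seed integer seed for tree growing.
#' @return A [SegmentationModel-class].
#' @export
trainClassifier <- function(train, nTrees = 200, mtry = NULL, maxDepth = 0,
                            seed = 1L) {
  stopifnot(inherits(train, "trainingSet"))
  if (nTrees < 1) stop("nTrees must be >= 1")
  if (length(unique(train$labels)) < 2L)
    stop("training set contains a single class; at least two are required")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(train$features))))
  df <- as.data.frame(train$features)
  df$.label <- factor(train$labels, levels = sort(unique(train$labels)))
  fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                        num.trees = nTrees, mtry = mtry,
                        max.depth = maxDepth, probability = TRUE,
                        seed = seed, num.threads = 1)
  new("SegmentationModel", forest = fit,
      featureNames = train$featureNames,
      config = list(nTrees = nTrees, mtry = mtry, maxDepth = maxDepth,
                    seed = seed))
}

#' Per-class probability maps for a feature stack
#'
#' Applies a trained classifier to every pixel of a stack. The model's
#' feature-name contract is enforced: a stack computed with different
#' features (or in a different order) is rejected.
#'
#' @param model a [SegmentationModel-class].
#' @param stack a [FeatureStack-class] with matching `featureNames`.
#' @return A [ProbabilityMaps-class] (`height x width x 4`, per-pixel sums 1;
#'   classes absent from training have probability 0).
#' @export
predictProbabilityMaps <- function(model, stack) {
  stopifnot(is(model, "SegmentationModel"), is(stack, "FeatureStack"))
  if (!identical(featureNames(model), featureNames(stack)))
    stop("feature names of the stack do not match the trained model")
  fa <- featureArray(stack)
  nr <- dim(fa)[1]; nc <- dim(fa)[2]
  fm <- matrix(fa, nr * nc, dim(fa)[3])
  colnames(fm) <- featureNames(stack)
  pr <- predict(model@forest, data = as.data.frame(fm),
                num.threads = 1)$predictions
  maps <- array(0, dim = c(nr, nc, 4L))
  for (j in seq_len(ncol(pr))) {
    cls <- as.integer(colnames(pr)[j])
    maps[, , cls + 1L] <- matrix(pr[, j], nr, nc)
  }
  new("ProbabilityMaps", maps = maps)
}

#' Label map from probability maps
#'
#' Per-pixel argmax over the four class probabilities; exact ties are broken
#' toward the lowest label index (deterministic). The result is invariant to
#' multiplying all maps by a positive constant.
#'
#' @param maps a [ProbabilityMaps-class] or a `height x width x 4` array.
#' @return Integer label matrix (0--3).
#' @export
classifyPixels <- function(maps) {
  m <- if (is(maps, "ProbabilityMaps")) probMaps(maps) else maps
  d <- dim(m)
  if (length(d) != 3L || d[3] != 4L)
    stop("maps must be height x width x 4")
  flat <- matrix(m, d[1] * d[2], 4L)
  matrix(max.col(flat, ties.method = "first") - 1L, d[1], d[2])
}

#' Grayscale thresholding baseline segmentation
#'
#' Converts the image to 8-bit luma (0.299 R + 0.587 G + 0.114 B) and bands
#' pixels by 1--3 strictly increasing cut points, assigning labels to bands
#' via `bandLabels`. This is the classical histogram-threshold alternative the
#' forest classifier is compared against.
#'
#' @param image a [Micrograph-class] or RGB array.
#' @param thresholds 1--3 strictly increasing grayscale cut points in
#'   `[0, 255]`; a pixel with luma `g` falls in band `sum(g > thresholds)`.
#' @param bandLabels integer labels assigned to the bands, darkest first;
#'   default `0:nBands-1`.
#' @return Integer label matrix.
#' @export
thresholdSegment <- function(image, thresholds, bandLabels = NULL) {
  px <- if (is(image, "Micrograph")) pixelData(image) else image
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || length(thresholds) > 3L)
    stop("between 1 and 3 thresholds are required")
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing")
  if (min(thresholds) < 0 || max(thresholds) > 255)
    stop("thresholds must lie in [0, 255]")
  g <- lumaGray(px)
  band <- matrix(findInterval(g, thresholds), nrow(g), ncol(g))
  if (is.null(bandLabels)) bandLabels <- seq_len(length(thresholds) + 1L) - 1L
  if (length(bandLabels) != length(thresholds) + 1L)
    stop("bandLabels must have one label per band")
  matrix(as.integer(bandLabels[band + 1L]), nrow(g), ncol(g))
}

## One-vs-rest metrics from a square confusion matrix (rows = real class).
metricsFromConfusion <- function(cm) {
  cm <- matrix(as.numeric(cm), nrow(cm))  # avoid integer overflow in MCC
  total <- sum(cm)
  classes <- seq_len(nrow(cm))
  out <- lapply(classes, function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- total - tp - fn - fp
    div <- function(num, den) if (den == 0) structure(0, flag = TRUE)
      else num / den
    tpRate <- div(tp, tp + fn)
    fpRate <- div(fp, fp + tn)
    precision <- div(tp, tp + fp)
    fden <- as.numeric(precision) + as.numeric(tpRate)
    f <- if (fden == 0) structure(0, flag = TRUE)
      else 2 * as.numeric(precision) * as.numeric(tpRate) / fden
    mden <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (mden == 0) structure(0, flag = TRUE)
      else (tp * tn - fp * fn) / sqrt(mden)
    c(tp_rate = as.numeric(tpRate), fp_rate = as.numeric(fpRate),
      precision = as.numeric(precision), recall = as.numeric(tpRate),
      f_measure = as.numeric(f), mcc = as.numeric(mcc),
      flagged = as.numeric(any(vapply(list(tpRate, fpRate, precision, f, mcc),
        function(z) isTRUE(attr(z, "flag")), logical(1)))))
  })
  m <- do.call(rbind, out)
  support <- rowSums(cm)
  w <- support / total
  avg <- colSums(m[, 1:6, drop = FALSE] * w)
  df <- as.data.frame(m)
  df$class <- seq_len(nrow(cm)) - 1L
  df$support <- support
  list(perClass = df[, c("class", "support", "tp_rate", "fp_rate",
                         "precision", "recall", "f_measure", "mcc",
                         "flagged")],
       weighted = avg,
       accuracy = sum(diag(cm)) / total)
}

#' Confusion matrix and classification metrics
#'
#' Tabulates a 4x4 confusion matrix (rows = real class, columns = predicted
#' class) and derives, per class, the one-vs-rest TP rate (= recall), FP
#' rate, precision, F-measure and Matthews correlation coefficient, plus
#' support-weighted averages and overall accuracy (trace / total). Metric
#' cells with a zero denominator are reported as 0 and flagged, so weighted
#' averages stay defined.
#'
#' @param truth,pred integer label matrices (0--3) of identical shape, or a
#'   precomputed 4x4 count matrix passed as `truth` with `pred = NULL`.
#' @return List with `confusion` (4x4 integer matrix), `perClass` metrics
#'   data frame, `weighted` averages, and `accuracy`.
#' @examples
#' cm <- rbind(c(5727, 220, 25, 10), c(92, 5630, 36, 16),
#'             c(7, 90, 1073, 4), c(1, 7, 9, 6361))
#' confusionAndMetrics(cm)$accuracy  # 0.973
#' @export
confusionAndMetrics <- function(truth, pred = NULL) {
  if (is.null(pred)) {
    cm <- as.matrix(truth)
    if (!all(dim(cm) == c(4L, 4L)) || any(cm < 0))
      stop("a precomputed confusion matrix must be 4 x 4 and nonnegative")
    ## caller-supplied counts: keep the caller's class order and names
    nms <- rownames(cm) %||% paste0("class", 1:4)
    res <- metricsFromConfusion(cm)
    res$perClass$class <- nms
    dimnames(cm) <- list(real = nms, predicted = colnames(cm) %||% nms)
    return(c(list(confusion = cm), res))
  } else {
    checkLabelMask(truth, "truth"); checkLabelMask(pred, "pred")
    if (!all(dim(truth) == dim(pred)))
      stop("truth and pred have different shapes")
    cm <- matrix(0L, 4L, 4L)
    tab <- table(factor(truth, levels = 0:3), factor(pred, levels = 0:3))
    cm[] <- as.integer(tab)
    dimnames(cm) <- list(real = names(roiLabels()),
                         predicted = names(roiLabels()))
  }
  res <- metricsFromConfusion(cm)
  res$perClass$class <- names(roiLabels())
  c(list(confusion = cm), res)
}

#' Stratified k-fold cross-validation of the pixel classifier
#'
#' Splits the training pixels into `k` folds (stratified by class where each
#' class has at least `k` members, plain random folds otherwise, with a
#' warning), fits the forest on each training remainder, predicts the held
#' fold, and pools the out-of-fold predictions into a single confusion matrix
#' from which the metric suite is computed.
#'
#' @param train a `"trainingSet"`.
#' @param k number of folds (default 10).
#' @param seed fold-assignment and tree seed.
#' @param ... forest settings passed to [trainClassifier()].
#' @return As [confusionAndMetrics()], plus `folds` (the assignment).
#' @export
crossValidate <- function(train, k = 10, seed = 1L, ...) {
  stopifnot(inherits(train, "trainingSet"))
  n <- length(train$labels)
  if (n < k) stop("need at least k observations")
  folds <- withSeed(seed, {
    counts <- table(train$labels)
    if (all(counts >= k)) {
      f <- integer(n)
      for (cls in as.integer(names(counts))) {
        idx <- which(train$labels == cls)
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      f
    } else {
      warning("some class has fewer than k pixels; using plain random folds")
      sample(rep_len(seq_len(k), n))
    }
  })
  predAll <- integer(n)
  for (fold in seq_len(k)) {
    hold <- folds == fold
    sub <- structure(list(features = train$features[!hold, , drop = FALSE],
                          labels = train$labels[!hold],
                          coords = train$coords[!hold, , drop = FALSE],
                          featureNames = train$featureNames, seed = seed),
                     class = "trainingSet")
    model <- trainClassifier(sub, seed = seed, ...)
    pr <- predict(model@forest,
                  data = as.data.frame(train$features[hold, , drop = FALSE]),
                  num.threads = 1)$predictions
    lev <- as.integer(colnames(pr))
    predAll[hold] <- lev[max.col(pr, ties.method = "first")]
  }
  cm <- matrix(0L, 4L, 4L)
  tab <- table(factor(train$labels, levels = 0:3),
               factor(predAll, levels = 0:3))
  cm[] <- as.integer(tab)
  dimnames(cm) <- list(real = names(roiLabels()),
                       predicted = names(roiLabels()))
  res <- metricsFromConfusion(cm)
  res$perClass$class <- names(roiLabels())
  c(list(confusion = cm, folds = folds), res)
}

#' Per-image misclassification error for one region of interest
#'
#' The square root of the number of pixels whose one-vs-rest membership in
#' `roiClass` differs between the ground-truth and predicted masks. Used to
#' compare the forest and thresholding segmentations image by image.
#'
#' @param truth,pred integer label matrices of identical shape.
#' @param roiClass the class (0--3) whose membership is compared.
#' @return Nonnegative scalar.
#' @export
misclassificationError <- function(truth, pred, roiClass = 1L) {
  checkLabelMask(truth, "truth"); checkLabelMask(pred, "pred")
  if (!all(dim(truth) == dim(pred)))
    stop("truth and pred have different shapes")
  sqrt(sum((truth == roiClass) != (pred == roiClass)))
}
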