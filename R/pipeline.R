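## End-to-end orchestration: synthetic series (or an image directory) ->
## texture features -> forest segmentation -> object features -> kinetic and
## regression models -> CSV/JSON report bundle with a manifest.

#' Assemble a pipeline configuration
#'
#' Collects every tunable of the pipeline with its documented default. The
#' synthetic branch defines, per experimental group, the composition trend of
#' the image series and the logistic-mixture parameters of the mass-loss
#' curve; the defaults emulate a 44-day culture in which the
#' extracellular-matrix fraction grows at the expense of collagen, with
#' kinetics in the range reported for collagen scaffolds (an early component
#' saturating near 50% and a later one near 23%, CO losing ~30% almost
#' immediately).
#'
#' @param outDir output directory (created if needed).
#' @param times acquisition days.
#' @param groups character vector of groups to simulate.
#' @param imageParams template [syntheticImageParams()].
#' @param texture list: `sigma`, `r`, `nBins`.
#' @param forest list: `nTrees`, `nPerClass` (training pixels per class).
#' @param roi list: `pixelSize` (um/px; defaults to 300/189), `minSizePx`,
#'   `roiClass` (object-feature region, default extracellular matrix = 2).
#' @param models list: `k` (mixture components), `B` (bootstrap resamples),
#'   `folds` (CV folds), `massLossTheta` (named list per group),
#'   `massLossNoiseSd`.
#' @param inputDir optional directory of real PNG/TIFF micrographs named
#'   `<group>_t<day>.<ext>`; when given, the synthetic branch is skipped and
#'   ground-truth masks (subdirectory `masks/`, same file names) are used
#'   for training when present.
#' @param seed global seed; every stage derives its own seed from it.
#' @return List of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(outDir = tempfile("scaffoldquant"),
    times = c(0, 11, 22, 33, 44),
    groups = c("CCO", "CCT"),
    imageParams = syntheticImageParams(width = 96, height = 96),
    texture = list(sigma = 2, r = 4, nBins = 256),
    forest = list(nTrees = 200, nPerClass = 150),
    roi = list(pixelSize = NULL, minSizePx = 10, roiClass = 2L),
    models = list(k = 2, B = 200, folds = 3,
                  massLossTheta = list(
                    CCO = c(50.2, 1.7, 1.0, 23.5, 16.3, 1.3),
                    CCT = c(52.5, 2.5, 1.2, 21.7, 16.9, 3.7),
                    CO = c(30, 1, 0.5)),
                  massLossNoiseSd = 1, massLossReps = 3),
    inputDir = NULL, seed = 1L) {
  structure(list(outDir = outDir, times = times, groups = groups,
                 imageParams = imageParams, texture = texture,
                 forest = forest, roi = roi, models = models,
                 inputDir = inputDir, seed = as.integer(seed)),
            class = "pipelineConfig")
}

## Linear fractions trend: collagen shrinks, matrix grows, nuclei constant.
defaultTrend <- function(times) {
  s <- (times - min(times)) / max(diff(range(times)), 1)
  cbind(background = 0.27 - 0.05 * s,
        collagen = 0.50 - 0.30 * s,
        matrix = 0.15 + 0.35 * s,
        nuclei = 0.08 + 0 * s)
}

#' Run the full analysis pipeline
#'
#' Executes images -> segmentation -> features -> models and writes a report
#' bundle under `config$outDir`: per image a probability-map TIFF, predicted
#' label mask, and object table; globally the segmentation metric report,
#' the logistic-mixture fit with bootstrap intervals, the univariate and
#' multivariate linear models with lmg importance shares, the cross-validated
#' observed-vs-predicted table, and a JSON manifest recording seeds, package
#' version, configuration hash and any per-image warnings. A failing image is
#' isolated (recorded in the manifest) and the run continues.
#'
#' When `config$roi$pixelSize` is `NULL` the default microscope calibration
#' of 300/189 um/px is used and a notice is logged in the manifest.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with the image summary table, the model fits and
#'   the manifest.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  notices <- character(0)
  pixelSize <- config$roi$pixelSize
  if (is.null(pixelSize)) {
    pixelSize <- 300 / 189
    notices <- c(notices,
                 "pixelSize missing; defaulting to 300/189 um/px")
  }

  ## ---- acquire images ----
  frames <- list()
  if (is.null(config$inputDir)) {
    for (g in seq_along(config$groups)) {
      grp <- config$groups[g]
      tmpl <- config$imageParams
      tmpl$pixelSize <- pixelSize
      series <- generateSeries(config$times, defaultTrend(config$times),
                               template = tmpl,
                               seed = config$seed + 104729L * g)
      for (fr in series) {
        fr$micrograph@group <- grp
        fr$group <- grp
        frames[[length(frames) + 1L]] <- fr
      }
    }
  } else {
    files <- list.files(config$inputDir, pattern = "\\.(png|tif|tiff)$",
                        full.names = TRUE, ignore.case = TRUE)
    if (!length(files)) stop("no PNG/TIFF images in ", config$inputDir)
    for (f in files) {
      nm <- sub("\\.[^.]+$", "", basename(f))
      parts <- strsplit(nm, "_t")[[1]]
      tm <- suppressWarnings(as.numeric(parts[2]))
      mg <- readMicrograph(f, pixelSize = pixelSize, time = tm,
                           group = parts[1])
      maskFile <- file.path(config$inputDir, "masks", basename(f))
      msk <- if (file.exists(maskFile)) {
        m <- EBImage::imageData(EBImage::readImage(maskFile))
        matrix(as.integer(round(t(m) * 255)), ncol = nrow(m))
      } else NULL
      frames[[length(frames) + 1L]] <- list(micrograph = mg, mask = msk,
                                            time = tm, group = parts[1])
    }
  }

  ## ---- segmentation model from the first frame with a mask ----
  trainIdx <- which(vapply(frames, function(f) !is.null(f$mask),
                           logical(1)))[1]
  if (is.na(trainIdx))
    stop("no ground-truth mask available to train the classifier")
  trainStack <- buildFeatureStack(frames[[trainIdx]]$micrograph,
                                  sigma = config$texture$sigma,
                                  r = config$texture$r,
                                  nBins = config$texture$nBins)
  train <- sampleTrainingPixels(trainStack, frames[[trainIdx]]$mask,
                                nPerClass = config$forest$nPerClass,
                                seed = config$seed + 1L)
  model <- trainClassifier(train, nTrees = config$forest$nTrees,
                           seed = config$seed + 2L)

  ## ---- per-image segmentation and object features ----
  summaries <- list(); failures <- list(); metricRows <- list()
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    tag <- sprintf("%s_t%02d", fr$group, round(fr$time))
    res <- tryCatch({
      stack <- if (i == trainIdx) trainStack else
        buildFeatureStack(fr$micrograph, sigma = config$texture$sigma,
                          r = config$texture$r,
                          nBins = config$texture$nBins)
      maps <- predictProbabilityMaps(model, stack)
      pred <- classifyPixels(maps)
      EBImage::writeImage(EBImage::Image(aperm(probMaps(maps), c(2, 1, 3))),
                          file.path(config$outDir,
                                    paste0(tag, "_probmaps.tiff")))
      writeMicrograph(pred, file.path(config$outDir,
                                      paste0(tag, "_labels.tiff")))
      if (!is.null(fr$mask)) {
        cm <- confusionAndMetrics(fr$mask, pred)
        metricRows[[tag]] <- data.frame(image = tag,
          accuracy = cm$accuracy,
          misclass_err_collagen =
            misclassificationError(fr$mask, pred, roiLabels()["collagen"]))
      }
      roiBin <- pred == config$roi$roiClass
      objects <- extractObjects(roiBin, pixelScaleUm = pixelSize,
                                minSizePx = config$roi$minSizePx)
      utils::write.csv(objects,
                       file.path(config$outDir, paste0(tag, "_objects.csv")),
                       row.names = FALSE)
      summarizeImage(objects, fr$micrograph, roiBin, time = fr$time,
                     group = fr$group)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[tag]] <- conditionMessage(res)
    } else summaries[[length(summaries) + 1L]] <- res
  }
  summaryTab <- do.call(rbind, summaries)

  ## ---- mass-loss records ----
  reps <- config$models$massLossReps %||% 3L
  massLoss <- do.call(rbind, lapply(seq_along(config$groups), function(g) {
    grp <- config$groups[g]
    theta <- config$models$massLossTheta[[grp]]
    simulateMassLoss(theta, rep(config$times, each = reps),
                     noiseSd = config$models$massLossNoiseSd, group = grp,
                     seed = config$seed + 31L * g)
  }))
  massMean <- stats::aggregate(mass_loss_pct ~ time_days + group, massLoss,
                               mean)
  summaryTab <- merge(summaryTab, massMean, by = c("time_days", "group"),
                      sort = TRUE)
  utils::write.csv(summaryTab, file.path(config$outDir,
                                         "image_summaries.csv"),
                   row.names = FALSE)

  ## ---- kinetic fit (per first group) ----
  grp1 <- config$groups[1]
  rec1 <- massLoss[massLoss$group == grp1, ]
  mix <- tryCatch(
    fitMixture(rec1, k = config$models$k, seed = config$seed + 5L,
               deControl = list(generations = 120)),
    error = function(e) {
      notices <<- c(notices, paste0("mixture fit (", grp1, "): ",
                                    conditionMessage(e)))
      NULL
    })
  boot <- NULL
  if (!is.null(mix))
    boot <- tryCatch(
      withCallingHandlers(
        bootstrapParameters(mix, B = config$models$B,
                            seed = config$seed + 6L),
        warning = function(w) {
          notices <<- c(notices, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        notices <<- c(notices, paste0("bootstrap: ", conditionMessage(e)))
        NULL
      })
  gam <- fitGam(rec1$time_days, rec1$mass_loss_pct,
                L = min(10, length(unique(rec1$time_days)) - 3))
  if (!is.null(mix))
    jsonlite::write_json(list(
      group = grp1, k = mix$k, coefficients = mix$coefTable,
      bootstrap = if (!is.null(boot)) as.data.frame(boot) else NULL,
      r_squared = mix$rSquared,
      gam_r_squared = gam$rSquared, seed = config$seed),
      file.path(config$outDir, "mixture_fit.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")

  ## ---- regression models on image features ----
  lmOut <- NULL
  tab <- summaryTab[stats::complete.cases(
    summaryTab[, c("mean_area_um2", "mean_circularity", "gray_mode",
                   "mass_loss_pct")]), ]
  tab <- tab[tab$mean_area_um2 > 0 & tab$mean_circularity > 0 &
               tab$gray_mode > 0, ]
  if (nrow(tab) >= 8) {
    useGroup <- length(unique(tab$group)) > 1
    form <- if (useGroup)
      mass_loss_pct ~ group + log(mean_circularity) + log(gray_mode) +
        log(mean_area_um2)
    else
      mass_loss_pct ~ log(mean_circularity) + log(gray_mode) +
        log(mean_area_um2)
    multi <- fitLinear(form, tab)
    lmg <- relativeImportanceLMG(multi)
    cv <- kfoldPredictions(form, tab, k = config$models$folds,
                           seed = config$seed + 9L)
    areaFit <- fitLinear(mass_loss_pct ~ log(mean_area_um2), tab)
    circFit <- fitLinear(mass_loss_pct ~ log(mean_circularity), tab)
    utils::write.csv(cv, file.path(config$outDir, "cv_predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      multivariate = multi$coefTable, r_squared = multi$rSquared,
      lmg = as.list(lmg),
      area_model = areaFit$coefTable, area_r2 = areaFit$rSquared,
      circularity_model = circFit$coefTable, circ_r2 = circFit$rSquared),
      file.path(config$outDir, "linear_fits.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
    lmOut <- list(multivariate = multi, lmg = lmg, cv = cv,
                  area = areaFit, circularity = circFit)
  } else {
    notices <- c(notices,
                 "too few complete image summaries for regression models")
  }

  ## ---- segmentation metric report and manifest ----
  if (length(metricRows))
    utils::write.csv(do.call(rbind, metricRows),
                     file.path(config$outDir, "segmentation_metrics.csv"),
                     row.names = FALSE)
  cfgJson <- file.path(config$outDir, "config.json")
  cfgList <- config
  cfgList$imageParams <- unclass(cfgList$imageParams)
  jsonlite::write_json(unclass(cfgList), cfgJson, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  manifest <- list(
    package = "ScaffoldQuant",
    version = as.character(utils::packageVersion("ScaffoldQuant")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfgJson)),
    n_images = length(frames),
    failures = failures, notices = notices)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(summaries = summaryTab, mixture = mix, bootstrap = boot,
                 gam = gam, linear = lmOut, manifest = manifest,
                 model = model))
}
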