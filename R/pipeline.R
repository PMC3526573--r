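## End-to-end orchestration: greyscale -> BIF features -> random forest
## -> morphological cleanup -> colony metrics, plus batch quantification
## and evaluation against reference masks.

#' Pipeline configuration
#'
#' Collects every stage parameter with the standard defaults. The
#' fingerprint covers the feature configuration and changes whenever any
#' of scales, epsilon or window deviates.
#'
#' @param scales BIF filter scales (default 0.7 * c(1, 2, 4, 8)).
#' @param epsilon BIF flatness parameter (default 0.11).
#' @param window local histogram window (default 25).
#' @param nTrees,mtry random-forest parameters (defaults 20 and 5).
#' @param seed training seed.
#' @param minObject,minHoleFill cleanup size thresholds (4000 and 6000).
#' @param calibrationProfile profile name for input images.
#' @return list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(scales = 0.7 * c(1, 2, 4, 8), epsilon = 0.11,
                           window = 25L, nTrees = 20L, mtry = 5L,
                           seed = 1L, minObject = 4000L,
                           minHoleFill = 6000L,
                           calibrationProfile = "4x_1280x960") {
  cfg <- list(scales = scales, epsilon = epsilon, window = as.integer(window),
              nTrees = as.integer(nTrees), mtry = as.integer(mtry),
              seed = as.integer(seed), minObject = as.integer(minObject),
              minHoleFill = as.integer(minHoleFill),
              calibrationProfile = calibrationProfile)
  cfg$fingerprint <- featureFingerprint(scales, epsilon, window)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Segment one image
#'
#' Runs the full chain on a calibrated greyscale image: per-pixel BIF
#' histogram features, random-forest prediction, size-filter cleanup and
#' colony metrics. Stage timings are reported through \code{message()}
#' when \code{verbose}.
#'
#' @param image a \linkS4class{GrayImage} or a PNG/TIFF path.
#' @param model a \linkS4class{ForestModel}.
#' @param config a \code{\link{pipelineConfig}}; its feature settings
#'   must match the model's.
#' @param verbose log stage timings.
#' @return list(map = \linkS4class{ColonyLabelMap},
#'   metrics = \linkS4class{ColonyMetrics}).
#' @export
segmentImage <- function(image, model, config = pipelineConfig(),
                         verbose = FALSE) {
  if (is.character(image))
    image <- loadImage(image, profile = config$calibrationProfile)
  if (!identical(config$fingerprint, model@fingerprint))
    stop("pipeline feature configuration does not match the model")
  tick <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    if (verbose)
      message(sprintf("[segment] %-10s %.2f s", label,
                      proc.time()[["elapsed"]] - t0))
    out
  }
  fs <- tick("features", pixelFeatures(image, config$scales,
                                       config$epsilon, config$window))
  raw <- tick("classify", predictMask(model, fs))
  map <- tick("cleanup", cleanupMask(raw, config$minObject,
                                     config$minHoleFill,
                                     calibration = calibration(image)))
  list(map = map, metrics = colonyMetrics(map))
}

#' Train a classifier under a pipeline configuration
#'
#' Thin wrapper tying \code{\link{buildTrainingSet}} /
#' \code{\link{trainColonyClassifier}} to the config's parameters.
#'
#' @param featureList,maskList training images' feature stacks and masks.
#' @param config a \code{\link{pipelineConfig}}.
#' @param pixelsPerImage sampled pixels per image.
#' @return a \linkS4class{ForestModel}.
#' @export
trainPipeline <- function(featureList, maskList, config = pipelineConfig(),
                          pixelsPerImage = 20000L) {
  ts <- buildTrainingSet(featureList, maskList,
                         pixelsPerImage = pixelsPerImage,
                         seed = config$seed)
  trainColonyClassifier(ts, nTrees = config$nTrees, mtry = config$mtry,
                        seed = config$seed)
}

#' Quantify a batch of images
#'
#' Segments every PNG/TIFF in a directory (or every element of a list)
#' and tabulates per-image colony counts, areas and confluency.
#'
#' @param images directory path, character vector of paths, or list of
#'   \linkS4class{GrayImage}s.
#' @param model a \linkS4class{ForestModel}.
#' @param config a \code{\link{pipelineConfig}}.
#' @return data.frame: image, n_colonies, total_area_mm2, mean_area_mm2,
#'   confluency.
#' @export
quantifyBatch <- function(images, model, config = pipelineConfig()) {
  if (is.character(images) && length(images) == 1L && dir.exists(images))
    images <- list.files(images, pattern = "\\.(png|tif|tiff)$",
                         full.names = TRUE, ignore.case = TRUE)
  if (length(images) < 1L)
    stop("no images to quantify")
  ids <- if (is.character(images)) basename(images)
         else sprintf("image%03d", seq_along(images))
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- if (is.character(images)) images[i] else images[[i]]
    res <- segmentImage(img, model, config)
    m <- res$metrics
    rows[[i]] <- data.frame(
      image = ids[i], n_colonies = m@nColonies,
      total_area_mm2 = m@totalArea,
      mean_area_mm2 = if (m@meanDefined) m@meanArea else NA_real_,
      confluency = m@confluency)
  }
  do.call(rbind, rows)
}

#' Evaluate predicted against reference mask files
#'
#' Pairs files by name between two directories; unmatched or
#' shape-mismatched files are reported with a warning and skipped.
#'
#' @param predDir,refDir directories of mask PNGs with matching names, or
#'   lists of masks.
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluateMasks <- function(predDir, refDir) {
  if (is.character(predDir)) {
    pf <- list.files(predDir, pattern = "\\.(png|tif|tiff)$",
                     full.names = TRUE)
    rf <- list.files(refDir, pattern = "\\.(png|tif|tiff)$",
                     full.names = TRUE)
    common <- intersect(basename(pf), basename(rf))
    missing <- setdiff(union(basename(pf), basename(rf)), common)
    if (length(missing))
      warning("unmatched mask files skipped: ",
              paste(missing, collapse = ", "))
    if (!length(common)) stop("no matched mask pairs")
    predL <- lapply(file.path(predDir, common), loadMask)
    refL <- lapply(file.path(refDir, common), loadMask)
    ids <- common
  } else {
    predL <- predDir; refL <- refDir
    ids <- names(predL)
  }
  ok <- mapply(function(p, r) identical(dim(as.matrix(p)), dim(as.matrix(r))),
               predL, refL)
  if (any(!ok)) {
    warning(sum(!ok), " shape-mismatched pair(s) excluded")
    predL <- predL[ok]; refL <- refL[ok]
    ids <- ids[ok]
  }
  confluencyReport(predL, refL, ids = ids)
}
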