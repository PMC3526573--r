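#' Accessors for ColonyQuant classes
#'
#' Small accessor generics; slot access from user code is discouraged.
#'
#' @param x an object of the documented classes.
#' @param object an object (for show methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @rdname accessors
#' @export
setGeneric("bifLabels", function(x) standardGeneric("bifLabels"))

#' @rdname accessors
#' @export
setGeneric("bifScales", function(x) standardGeneric("bifScales"))

#' @rdname accessors
#' @export
setGeneric("featureArray", function(x) standardGeneric("featureArray"))

#' @rdname accessors
#' @export
setGeneric("colonyMask", function(x) standardGeneric("colonyMask"))

#' @rdname accessors
#' @export
setGeneric("colonyLabels", function(x) standardGeneric("colonyLabels"))

#' @rdname accessors
#' @export
setGeneric("colonyAreas", function(x) standardGeneric("colonyAreas"))

#' @rdname accessors
#' @export
setGeneric("nColonies", function(x) standardGeneric("nColonies"))

#' @rdname accessors
#' @export
setGeneric("confluency", function(x) standardGeneric("confluency"))

#' @rdname accessors
#' @export
setGeneric("flowRate", function(x) standardGeneric("flowRate"))

#' Pixel F-score
#'
#' F = 2 TP / (2 TP + FP + FN): the harmonic mean of pixel precision and
#' recall between a predicted and a reference mask.
#'
#' @param x a ConfusionCounts object, or the TP count.
#' @param ... FP and FN counts when \code{x} is numeric.
#' @return F-score in [0, 1].
#' @export
setGeneric("fScore", function(x, ...) standardGeneric("fScore"))

setMethod("pixels", "GrayImage", function(x) x@pixels)
setMethod("calibration", "GrayImage", function(x) x@calibration)
setMethod("calibration", "ColonyLabelMap", function(x) x@calibration)
setMethod("bifLabels", "BIFStack", function(x) x@labels)
setMethod("bifScales", "BIFStack", function(x) x@scales)
setMethod("bifScales", "FeatureStack", function(x) x@scales)
setMethod("featureArray", "FeatureStack", function(x) x@features)
setMethod("colonyMask", "ColonyLabelMap", function(x) x@mask)
setMethod("colonyLabels", "ColonyLabelMap", function(x) x@labels)
setMethod("colonyAreas", "ColonyLabelMap", function(x) x@areasPx)
setMethod("nColonies", "ColonyLabelMap", function(x) length(x@areasPx))
setMethod("nColonies", "ColonyMetrics", function(x) x@nColonies)
setMethod("confluency", "ColonyMetrics", function(x) x@confluency)
setMethod("flowRate", "PerfusionConditions", function(x) x@flowRate)

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage %d x %d, calibration %.3g um^2/px (%s)\n",
              d[1L], d[2L], object@calibration, object@profile))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "BIFStack", function(object) {
  d <- dim(object@labels)
  cat(sprintf("BIFStack %d x %d, %d scale(s): %s; epsilon = %g\n",
              d[1L], d[2L], d[3L],
              paste(signif(object@scales, 3), collapse = ", "),
              object@epsilon))
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@features)
  cat(sprintf(
    "FeatureStack %d x %d, %d features (7 bins x %d scales), window %d\n",
    d[1L], d[2L], d[3L], length(object@scales), object@window))
})

setMethod("show", "ForestModel", function(object) {
  cat(sprintf("ForestModel: %d trees, mtry %d, seed %d\n",
              object@nTrees, object@mtry, object@seed))
  cat(sprintf("  features: %d scales, epsilon %g, window %d [%s]\n",
              length(object@featureConfig$scales),
              object@featureConfig$epsilon, object@featureConfig$window,
              substr(object@fingerprint, 1L, 8L)))
})

setMethod("show", "ColonyLabelMap", function(object) {
  d <- dim(object@mask)
  cat(sprintf("ColonyLabelMap %d x %d: %d colonies, %d colony pixels\n",
              d[1L], d[2L], length(object@areasPx), sum(object@mask)))
})

setMethod("show", "ColonyMetrics", function(object) {
  cat(sprintf(
    "ColonyMetrics: %d colonies, total %.4g mm^2, mean %.4g mm^2, confluency %.1f%%\n",
    object@nColonies, object@totalArea,
    if (object@meanDefined) object@meanArea else NA_real_,
    100 * object@confluency))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport over %d image(s)\n", nrow(object@perImage)))
  cat(sprintf("  mean F-score %.3f (SD %.3f)\n", object@meanF, object@sdF))
  cat(sprintf("  confluency bias %+.4f, 95%% CI [%.4f, %.4f]\n",
              object@bias, object@biasCI[1L], object@biasCI[2L]))
  cat(sprintf("  RMSE %.4f, precision %.4f\n", object@rmse,
              object@precisionStat))
})

setMethod("show", "PerfusionConditions", function(object) {
  cat(sprintf(
    "PerfusionConditions: Q = %.4g ul/h, chamber %.3g x %.3g mm, gap %.3g um\n",
    object@flowRate * 3600 / 1e-9, object@geometry@width * 1e3,
    object@geometry@length * 1e3, object@geometry@height * 1e6))
})
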