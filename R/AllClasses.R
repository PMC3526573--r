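#' @import methods
NULL

#' Calibrated greyscale image
#'
#' A real-valued luminance image together with its spatial calibration
#' (area covered by one pixel, in square micrometres). Phase-contrast
#' frames taken with a 4x objective at 1280x960 resolve 2.86 um^2 per
#' pixel; other optics require an explicit calibration.
#'
#' @slot pixels numeric matrix of luminance values (rows = image rows).
#' @slot calibration area per pixel in um^2; must be positive.
#' @slot profile name of the calibration profile the value came from, or
#'   \code{"custom"}.
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", calibration = "numeric",
                 profile = "character"),
  prototype(calibration = 2.86, profile = "4x_1280x960"),
  validity = function(object) {
    if (!is.numeric(object@pixels))
      return("pixels must be a numeric matrix")
    if (nrow(object@pixels) < 1L || ncol(object@pixels) < 1L)
      return("image must have at least one pixel")
    if (any(!is.finite(object@pixels)))
      return("pixel values must be finite")
    if (length(object@calibration) != 1L || !is.finite(object@calibration) ||
        object@calibration <= 0)
      return("calibration (um^2/pixel) must be a single positive number")
    TRUE
  })

#' Scale-normalised derivative-of-Gaussian jet
#'
#' Responses of an image to Gaussian-derivative filters up to second
#' order at a single scale sigma, each multiplied by sigma^(derivative
#' order). The six responses determine the local-symmetry (BIF) class of
#' every pixel.
#'
#' @slot c00,c10,c01,c20,c11,c02 numeric matrices: the smoothed image and
#'   its scale-normalised first and second derivatives (x then y order).
#' @slot sigma the filter scale in pixels.
#' @export
setClass("JetResponse",
  representation(c00 = "matrix", c10 = "matrix", c01 = "matrix",
                 c20 = "matrix", c11 = "matrix", c02 = "matrix",
                 sigma = "numeric"),
  validity = function(object) {
    d <- dim(object@c00)
    for (s in c("c10", "c01", "c20", "c11", "c02"))
      if (!identical(dim(slot(object, s)), d))
        return("all jet responses must share one shape")
    if (object@sigma <= 0) return("sigma must be positive")
    TRUE
  })

#' Per-pixel BIF labels across scales
#'
#' One plane of basic-image-feature class labels per analysis scale.
#' Classes: 1 flat, 2 slope, 3 dark blob, 4 light blob, 5 dark line,
#' 6 light line, 7 saddle.
#'
#' @slot labels integer array H x W x S with values in 1..7.
#' @slot scales numeric vector of sigma values, one per plane.
#' @slot epsilon flatness parameter used during classification.
#' @export
setClass("BIFStack",
  representation(labels = "array", scales = "numeric", epsilon = "numeric"),
  validity = function(object) {
    d <- dim(object@labels)
    if (length(d) != 3L) return("labels must be an H x W x S array")
    if (d[3L] != length(object@scales))
      return("one label plane per scale required")
    rng <- range(object@labels)
    if (rng[1L] < 1L || rng[2L] > 7L)
      return("BIF labels must lie in 1..7")
    if (object@epsilon <= 0) return("epsilon must be positive")
    TRUE
  })

#' Per-pixel local BIF histogram features
#'
#' For every pixel, a count histogram of the seven BIF classes inside a
#' centred square window, concatenated across scales in scale order. The
#' default four scales give 28 features per pixel.
#'
#' @slot features integer array H x W x (7 * S) of window counts.
#' @slot scales,epsilon feature configuration inherited from the stack.
#' @slot window odd window side length in pixels.
#' @export
setClass("FeatureStack",
  representation(features = "array", scales = "numeric",
                 epsilon = "numeric", window = "integer"),
  validity = function(object) {
    d <- dim(object@features)
    if (length(d) != 3L) return("features must be an H x W x F array")
    if (d[3L] != 7L * length(object@scales))
      return("feature planes must number 7 per scale")
    if (object@window %% 2L != 1L || object@window < 1L)
      return("window must be odd and >= 1")
    TRUE
  })

#' Labelled pixel training set
#'
#' Feature vectors with binary expert labels (1 = colony, 0 = background,
#' feeder cells included in background) and per-pixel provenance.
#'
#' @slot features numeric matrix N x F.
#' @slot labels integer vector of 0/1 class labels.
#' @slot provenance data.frame with columns image, row, col.
#' @slot featureConfig list(scales, epsilon, window) the features were
#'   computed with.
#' @export
setClass("TrainingSet",
  representation(features = "matrix", labels = "integer",
                 provenance = "data.frame", featureConfig = "list"),
  validity = function(object) {
    if (nrow(object@features) != length(object@labels))
      return("one label per feature row required")
    if (nrow(object@features) < 1L) return("training set is empty")
    if (!all(object@labels %in% c(0L, 1L)))
      return("labels must be 0 (background) or 1 (colony)")
    TRUE
  })

#' Fitted random-forest pixel classifier
#'
#' Wraps the fitted ensemble together with the feature configuration it
#' was trained under; prediction refuses feature stacks computed with a
#' different configuration.
#'
#' @slot forest the fitted randomForest object.
#' @slot nTrees,mtry forest parameters (defaults 20 and 5).
#' @slot seed integer seed used for training.
#' @slot fingerprint digest of the feature configuration.
#' @slot featureConfig list(scales, epsilon, window).
#' @export
setClass("ForestModel",
  representation(forest = "ANY", nTrees = "integer", mtry = "integer",
                 seed = "integer", fingerprint = "character",
                 featureConfig = "list"),
  validity = function(object) {
    if (object@nTrees < 1L) return("nTrees must be >= 1")
    nf <- 7L * length(object@featureConfig$scales)
    if (object@mtry < 1L || object@mtry > nf)
      return(sprintf("mtry must lie in 1..%d", nf))
    TRUE
  })

#' Cleaned colony mask with component labels
#'
#' Binary mask after size filtering and hole filling, its connected
#' components (8-connectivity) labelled 1..K, and per-colony pixel areas.
#'
#' @slot mask integer matrix of 0/1.
#' @slot labels integer matrix, 0 = background, 1..K = colony id.
#' @slot areasPx integer vector of per-colony pixel counts.
#' @slot calibration area per pixel in um^2.
#' @export
setClass("ColonyLabelMap",
  representation(mask = "matrix", labels = "matrix", areasPx = "integer",
                 calibration = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@mask), dim(object@labels)))
      return("mask and labels must share one shape")
    if (!all(object@mask %in% c(0L, 1L)))
      return("mask must be binary")
    if (sum(object@areasPx) != sum(object@mask == 1L))
      return("colony areas must sum to the mask's positive pixel count")
    if (object@calibration <= 0) return("calibration must be positive")
    TRUE
  })

#' Summary metrics for a labelled colony map
#'
#' @slot nColonies number of detected colonies.
#' @slot totalArea,meanArea areas in mm^2 (mean is 0 with
#'   \code{meanDefined = FALSE} when no colony was detected).
#' @slot confluency fraction of image pixels classified colony, in [0,1].
#' @slot meanDefined FALSE when nColonies is 0.
#' @export
setClass("ColonyMetrics",
  representation(nColonies = "integer", totalArea = "numeric",
                 meanArea = "numeric", confluency = "numeric",
                 meanDefined = "logical"),
  validity = function(object) {
    if (object@confluency < 0 || object@confluency > 1)
      return("confluency must lie in [0,1]")
    if (object@totalArea < 0) return("areas must be non-negative")
    TRUE
  })

#' Pixel-level confusion counts
#'
#' @slot tp,fp,fn,tn true/false positive/negative pixel counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric"),
  validity = function(object) {
    v <- c(object@tp, object@fp, object@fn, object@tn)
    if (any(v < 0)) return("counts must be non-negative")
    TRUE
  })

#' Segmentation evaluation report
#'
#' Per-image F-scores and confluency errors against reference masks, with
#' summary statistics: bias (mean signed confluency error), its 95%
#' t-interval, RMSE, and precision = sqrt(RMSE^2 - bias^2).
#'
#' @slot perImage data.frame with columns id, fscore, confPred, confRef,
#'   delta.
#' @slot meanF,sdF mean and SD of per-image F-scores.
#' @slot bias,rmse,precisionStat confluency-error summaries.
#' @slot biasCI length-2 numeric (95% CI for the bias), NA when fewer
#'   than two image pairs were supplied.
#' @export
setClass("EvaluationReport",
  representation(perImage = "data.frame", meanF = "numeric", sdF = "numeric",
                 bias = "numeric", biasCI = "numeric", rmse = "numeric",
                 precisionStat = "numeric"),
  validity = function(object) {
    if (length(object@biasCI) != 2L) return("biasCI must have length 2")
    TRUE
  })

#' Parallel-plate culture chamber geometry
#'
#' Dimensions in metres. Defaults describe a 13 mm x 4 mm chamber of
#' 450 um height whose culture plane is recessed 120 um below the flow
#' channels (the recess is informational; the analytical shear model uses
#' the full gap).
#'
#' @slot width chamber width across the flow (m).
#' @slot length chamber length along the flow (m).
#' @slot height chamber gap height (m).
#' @slot recess elevation of the flow layer above the culture plane (m).
#' @export
setClass("ChamberGeometry",
  representation(width = "numeric", length = "numeric", height = "numeric",
                 recess = "numeric"),
  prototype(width = 13e-3, length = 4e-3, height = 450e-6, recess = 120e-6),
  validity = function(object) {
    if (any(c(object@width, object@length, object@height) <= 0))
      return("chamber dimensions must be positive")
    TRUE
  })

#' Culture-medium fluid properties
#'
#' Defaults are water at 37 degrees C: dynamic viscosity 6.96e-4 Pa s and
#' density 993.2 kg m^-3.
#'
#' @slot viscosity dynamic viscosity (Pa s).
#' @slot density density (kg m^-3).
#' @export
setClass("FluidProperties",
  representation(viscosity = "numeric", density = "numeric"),
  prototype(viscosity = 6.96e-4, density = 993.2),
  validity = function(object) {
    if (object@viscosity <= 0) return("viscosity must be positive")
    if (object@density <= 0) return("density must be positive")
    TRUE
  })

#' Perfusion operating conditions
#'
#' Chamber geometry, fluid properties and the volumetric flow rate
#' (stored in SI, m^3 s^-1; the default corresponds to 300 ul h^-1).
#'
#' @slot flowRate volumetric flow rate (m^3 s^-1).
#' @slot geometry a ChamberGeometry.
#' @slot fluid a FluidProperties.
#' @export
setClass("PerfusionConditions",
  representation(flowRate = "numeric", geometry = "ChamberGeometry",
                 fluid = "FluidProperties"),
  prototype(flowRate = 300e-9 / 3600),
  validity = function(object) {
    if (object@flowRate < 0) return("flow rate must be non-negative")
    TRUE
  })

#' Synthetic two-texture image generator configuration
#'
#' Parameters of the procedural phase-contrast emulator: dense
#' fine-grained speckle inside colonies against sparse elongated strokes
#' (fibroblast-like) on the background, over an unevenly illuminated,
#' noisy field, with a bright halo at colony rims.
#'
#' @slot size image height and width in pixels.
#' @slot nColonies inclusive range for the number of colonies drawn.
#' @slot radiusRange colony radius range in pixels.
#' @slot boundaryIrregularity relative amplitude of the random radial
#'   perturbation of colony outlines (0 = perfect discs).
#' @slot colonyContrast SD of the fine granular texture inside colonies.
#' @slot colonyBlobDensity stamped micro-blob count per colony pixel.
#' @slot colonyBlobSize blob radius range in pixels.
#' @slot strokeDensity stroke count per background pixel.
#' @slot strokeLength,strokeWidth stroke geometry ranges in pixels.
#' @slot strokeContrast intensity amplitude of background strokes.
#' @slot illuminationAmplitude peak-to-centre amplitude of the smooth
#'   illumination field.
#' @slot noiseSd SD of additive pixel noise.
#' @slot haloStrength brightness added in a thin band outside colony rims.
#' @slot calibration area per pixel (um^2) attached to generated images.
#' @slot seed integer seed fixing the full sample path.
#' @export
setClass("GeneratorConfig",
  representation(size = "integer", nColonies = "integer",
                 radiusRange = "numeric", boundaryIrregularity = "numeric",
                 colonyContrast = "numeric", colonyBlobDensity = "numeric",
                 colonyBlobSize = "numeric", strokeDensity = "numeric",
                 strokeLength = "numeric", strokeWidth = "numeric",
                 strokeContrast = "numeric",
                 illuminationAmplitude = "numeric", noiseSd = "numeric",
                 haloStrength = "numeric", calibration = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (any(object@size < 16L)) return("image size must be at least 16 px")
    if (any(object@nColonies < 0L)) return("colony count must be >= 0")
    if (max(object@radiusRange) * 2 > min(object@size))
      return("colony radius does not fit in the image")
    if (any(c(object@colonyBlobDensity, object@strokeDensity,
              object@noiseSd, object@haloStrength) < 0))
      return("densities, noise and halo must be non-negative")
    TRUE
  })
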