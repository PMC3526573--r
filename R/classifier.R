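## Random-forest pixel classifier over local BIF histogram features.

#' Assemble a training set from feature stacks and reference masks
#'
#' Samples pixels from one or more (features, mask) pairs, optionally
#' balancing the two classes 1:1, and records per-pixel provenance.
#'
#' @param featureList list of \linkS4class{FeatureStack} objects.
#' @param maskList list of 0/1 reference masks matching the stacks.
#' @param pixelsPerImage pixels sampled from each image (split over the
#'   classes when balancing).
#' @param balance sample the two classes equally (default TRUE). A class
#'   that is present but smaller than its quota is resampled with
#'   replacement (with a warning); a class that is absent is an error.
#' @param imageIds optional character ids recorded in provenance.
#' @param seed integer seed for the sampling.
#' @return a \linkS4class{TrainingSet}.
#' @export
buildTrainingSet <- function(featureList, maskList,
                             pixelsPerImage = 20000L, balance = TRUE,
                             imageIds = NULL, seed = 1L) {
  stopifnot(length(featureList) == length(maskList),
            length(featureList) >= 1L)
  if (is.null(imageIds)) imageIds <- sprintf("img%03d", seq_along(maskList))
  cfg <- list(scales = featureList[[1L]]@scales,
              epsilon = featureList[[1L]]@epsilon,
              window = featureList[[1L]]@window)
  featL <- list(); labL <- list(); provL <- list()
  set.seed(as.integer(seed))
  for (i in seq_along(featureList)) {
    fs <- featureList[[i]]
    mask <- maskList[[i]]
    d <- dim(fs@features)
    if (!identical(dim(mask), d[1:2]))
      stop("mask and feature stack shapes differ for image ", imageIds[i])
    lab <- as.integer(as.vector(mask) > 0)
    if (balance) {
      pos <- which(lab == 1L); neg <- which(lab == 0L)
      k <- pixelsPerImage %/% 2L
      if (length(pos) == 0L || length(neg) == 0L)
        stop(sprintf(
          "balanced sampling requires both classes; image %s has only one",
          imageIds[i]))
      # a scarce (but present) class is bootstrapped up to the quota so
      # the 1:1 balance holds even for frames with one small colony
      if (length(pos) < k || length(neg) < k)
        warning(sprintf(
          "image %s: class with %d pixels resampled with replacement to %d",
          imageIds[i], min(length(pos), length(neg)), k))
      take <- c(sample(pos, k, replace = length(pos) < k),
                sample(neg, k, replace = length(neg) < k))
    } else {
      if (length(lab) < pixelsPerImage)
        stop("image ", imageIds[i], " has fewer pixels than requested")
      take <- sample(length(lab), pixelsPerImage)
    }
    fm <- featureMatrix(fs)
    featL[[i]] <- fm[take, , drop = FALSE]
    labL[[i]] <- lab[take]
    provL[[i]] <- data.frame(
      image = imageIds[i],
      row = ((take - 1L) %% d[1L]) + 1L,
      col = ((take - 1L) %/% d[1L]) + 1L)
  }
  new("TrainingSet", features = do.call(rbind, featL),
      labels = do.call(c, labL), provenance = do.call(rbind, provL),
      featureConfig = cfg)
}

#' Train the random-forest pixel classifier
#'
#' Fits a random forest on labelled feature vectors; defaults are 20
#' trees with 5 variables sampled at each split. The fitted model stores
#' a fingerprint of the feature configuration (scales, epsilon, window)
#' and later refuses to predict on features computed differently.
#'
#' @param training a \linkS4class{TrainingSet}; must contain both classes.
#' @param nTrees number of trees (default 20).
#' @param mtry variables sampled per split (default 5); must not exceed
#'   the feature count.
#' @param seed integer seed; training is reproducible given the seed.
#' @return a \linkS4class{ForestModel}.
#' @export
trainColonyClassifier <- function(training, nTrees = 20L, mtry = 5L,
                                  seed = 1L) {
  if (!is(training, "TrainingSet")) stop("expected a TrainingSet")
  if (length(unique(training@labels)) < 2L)
    stop("training set must contain both classes")
  if (any(!is.finite(training@features)))
    stop("training features must be finite")
  nf <- ncol(training@features)
  if (mtry > nf)
    stop(sprintf("mtry (%d) exceeds the feature count (%d)", mtry, nf))
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(
    x = training@features,
    y = factor(training@labels, levels = c(0L, 1L)),
    ntree = as.integer(nTrees), mtry = as.integer(mtry))
  cfg <- training@featureConfig
  new("ForestModel", forest = fit, nTrees = as.integer(nTrees),
      mtry = as.integer(mtry), seed = as.integer(seed),
      fingerprint = featureFingerprint(cfg$scales, cfg$epsilon, cfg$window),
      featureConfig = cfg)
}

#' Predict a raw binary colony mask
#'
#' Applies the fitted forest to every pixel's feature vector; the class
#' receiving the majority of tree votes wins (threshold 0.5). The result
#' is the raw map before morphological cleanup.
#'
#' @param model a \linkS4class{ForestModel}.
#' @param features a \linkS4class{FeatureStack} (or plain feature matrix
#'   for tabular prediction).
#' @param probability also return the per-pixel colony vote fraction.
#' @return integer 0/1 matrix (1 = colony); with \code{probability=TRUE}
#'   a list(mask, prob).
#' @export
predictMask <- function(model, features, probability = FALSE) {
  if (!is(model, "ForestModel")) stop("expected a ForestModel")
  if (is(features, "FeatureStack")) {
    fp <- featureFingerprint(features@scales, features@epsilon,
                             features@window)
    if (!identical(fp, model@fingerprint))
      stop("feature configuration does not match the model fingerprint: ",
           "recompute features with the model's scales/epsilon/window")
    fm <- featureMatrix(features)
    d <- dim(features@features)[1:2]
  } else {
    fm <- as.matrix(features)
    d <- NULL
  }
  votes <- predict(model@forest, fm, type = "prob")[, "1"]
  lab <- as.integer(votes > 0.5)
  if (!is.null(d)) {
    lab <- matrix(lab, d[1L], d[2L])
    if (probability) return(list(mask = lab, prob = matrix(votes, d[1L], d[2L])))
  } else if (probability) {
    return(list(mask = lab, prob = votes))
  }
  lab
}

#' Persist / restore a fitted classifier
#'
#' The on-disk form is a versioned container embedding the
#' feature-configuration fingerprint, so a restored model keeps refusing
#' mismatched feature stacks.
#'
#' @param model a \linkS4class{ForestModel}.
#' @param path file path for the model archive.
#' @return \code{saveModel}: \code{path} invisibly; \code{loadModel}: the
#'   restored \linkS4class{ForestModel}.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ForestModel"))
  saveRDS(list(format = "ColonyQuant-forest", version = 1L,
               nTrees = model@nTrees, mtry = model@mtry, seed = model@seed,
               fingerprint = model@fingerprint,
               featureConfig = model@featureConfig,
               forest = model@forest),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "ColonyQuant-forest"))
    stop("not a ColonyQuant model archive: ", path)
  new("ForestModel", forest = obj$forest, nTrees = obj$nTrees,
      mtry = obj$mtry, seed = obj$seed, fingerprint = obj$fingerprint,
      featureConfig = obj$featureConfig)
}
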