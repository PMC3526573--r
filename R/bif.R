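## Derivative-of-Gaussian jets and seven-class basic image features (BIFs).
##
## All filtering is separable convolution with half-sample symmetric
## (reflective) padding; kernels are sampled Gaussians and their analytic
## derivatives truncated at 4 sigma.

# map out-of-range indices onto 1..n by repeated reflection about the edges
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  as.integer(ifelse(j < n, j + 1L, 2L * n - j))
}

# true 1-D convolution along the given margin, reflective padding
convolve1d <- function(x, kernel, margin) {
  p <- (length(kernel) - 1L) %/% 2L
  kf <- rev(kernel)  # correlation with the flipped kernel == convolution
  out <- matrix(0, nrow(x), ncol(x))
  if (margin == 1L) {
    n <- nrow(x)
    xp <- x[reflectIndex(seq.int(1L - p, n + p), n), , drop = FALSE]
    for (k in seq_along(kf))
      out <- out + kf[k] * xp[(k - 1L) + seq_len(n), , drop = FALSE]
  } else {
    n <- ncol(x)
    xp <- x[, reflectIndex(seq.int(1L - p, n + p), n), drop = FALSE]
    for (k in seq_along(kf))
      out <- out + kf[k] * xp[, (k - 1L) + seq_len(n), drop = FALSE]
  }
  out
}

# sampled Gaussian (sum-normalised) and its analytic derivatives
gaussianKernel <- function(sigma, order = 0L, truncate = 4) {
  r <- max(1L, ceiling(truncate * sigma))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g,  # odd: sums to zero by symmetry
    "2" = {
      g2 <- (x^2 - sigma^2) / sigma^4 * g
      g2 - sum(g2) / length(g2)  # zero-sum: constants map exactly to 0
    },
    stop("derivative order must be 0, 1 or 2"))
}

#' Scale-normalised Gaussian-derivative jet
#'
#' Convolves the image with derivative-of-Gaussian filters up to second
#' order at scale \code{sigma} and multiplies each response by
#' sigma^(derivative order). The six responses (smoothed image, two first
#' and three second derivatives) carry the local-symmetry information the
#' BIF classification reads out.
#'
#' @param img a \linkS4class{GrayImage} or numeric matrix.
#' @param sigma filter scale in pixels; must be positive.
#' @return a \linkS4class{JetResponse}.
#' @export
jet <- function(img, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number")
  m <- if (is(img, "GrayImage")) pixels(img) else img
  g0 <- gaussianKernel(sigma, 0L)
  g1 <- gaussianKernel(sigma, 1L)
  g2 <- gaussianKernel(sigma, 2L)
  # x = column direction, y = row direction; separable passes
  sx0 <- convolve1d(m, g0, 2L)
  sx1 <- convolve1d(m, g1, 2L)
  sx2 <- convolve1d(m, g2, 2L)
  new("JetResponse",
      c00 = convolve1d(sx0, g0, 1L),
      c10 = sigma * convolve1d(sx1, g0, 1L),
      c01 = sigma * convolve1d(sx0, g1, 1L),
      c20 = sigma^2 * convolve1d(sx2, g0, 1L),
      c11 = sigma^2 * convolve1d(sx1, g1, 1L),
      c02 = sigma^2 * convolve1d(sx0, g2, 1L),
      sigma = sigma)
}

#' Classify each pixel into one of seven BIF classes
#'
#' Each pixel is assigned the local-symmetry class whose score is
#' largest. With lambda = c20 + c02 and
#' gamma = sqrt((c20 - c02)^2 + 4 c11^2) the scores are: flat
#' \code{epsilon * c00}; slope \code{2 sqrt(c10^2 + c01^2)}; dark blob
#' \code{+lambda}; light blob \code{-lambda}; dark line
#' \code{(gamma + lambda)/sqrt(2)}; light line
#' \code{(gamma - lambda)/sqrt(2)}; saddle \code{gamma}. A positive
#' Laplacian (local intensity minimum) therefore reads "dark". All seven
#' scores scale linearly with image intensity, so the labels are
#' invariant to global intensity rescaling; \code{epsilon} alone decides
#' how readily weak structure is absorbed into "flat". Ties take the
#' lowest class index.
#'
#' @param jetr a \linkS4class{JetResponse}.
#' @param epsilon positive flatness parameter (default 0.11).
#' @return integer matrix of labels in 1..7 (flat, slope, dark blob,
#'   light blob, dark line, light line, saddle).
#' @export
classifyBIF <- function(jetr, epsilon = 0.11) {
  if (!is(jetr, "JetResponse")) stop("expected a JetResponse")
  if (epsilon <= 0) stop("epsilon must be positive")
  lam <- jetr@c20 + jetr@c02
  gam <- sqrt((jetr@c20 - jetr@c02)^2 + 4 * jetr@c11^2)
  n <- length(lam)
  scores <- cbind(
    as.vector(epsilon * jetr@c00),
    as.vector(2 * sqrt(jetr@c10^2 + jetr@c01^2)),
    as.vector(lam),
    as.vector(-lam),
    as.vector((gam + lam) / sqrt(2)),
    as.vector((gam - lam) / sqrt(2)),
    as.vector(gam))
  lab <- max.col(scores, ties.method = "first")
  matrix(as.integer(lab), nrow(lam), ncol(lam))
}

#' Multiscale BIF stack
#'
#' Classifies every pixel at each requested scale. Defaults follow the
#' four-octave scheme 0.7 * (1, 2, 4, 8) with epsilon 0.11.
#'
#' @param img a \linkS4class{GrayImage} or numeric matrix.
#' @param scales positive sigma values, one plane per scale.
#' @param epsilon flatness parameter.
#' @return a \linkS4class{BIFStack}.
#' @export
bifStack <- function(img, scales = 0.7 * c(1, 2, 4, 8), epsilon = 0.11) {
  if (length(scales) < 1L) stop("at least one scale is required")
  m <- if (is(img, "GrayImage")) pixels(img) else img
  planes <- array(0L, dim = c(nrow(m), ncol(m), length(scales)))
  for (s in seq_along(scales))
    planes[, , s] <- classifyBIF(jet(m, scales[s]), epsilon)
  new("BIFStack", labels = planes, scales = scales, epsilon = epsilon)
}

#' Local BIF histogram features
#'
#' For every pixel, counts the seven BIF classes inside a centred,
#' uniformly weighted \code{window} x \code{window} neighbourhood
#' (reflective padding at the borders) and concatenates the per-scale
#' histograms in scale order. The default four scales and 25 px window
#' give 28 raw counts per pixel, each scale's seven bins summing to 625.
#'
#' @param bifs a \linkS4class{BIFStack}.
#' @param window odd window side length (default 25).
#' @return a \linkS4class{FeatureStack}.
#' @export
featureStack <- function(bifs, window = 25L) {
  if (!is(bifs, "BIFStack")) stop("expected a BIFStack")
  window <- as.integer(window)
  if (window < 1L || window %% 2L != 1L)
    stop("window must be an odd integer >= 1")
  d <- dim(bifs@labels)
  nS <- d[3L]
  ones <- rep(1, window)
  feats <- array(0L, dim = c(d[1L], d[2L], 7L * nS))
  for (s in seq_len(nS)) {
    plane <- bifs@labels[, , s]
    for (cls in 1:7) {
      ind <- matrix(as.numeric(plane == cls), d[1L], d[2L])
      cnt <- convolve1d(convolve1d(ind, ones, 2L), ones, 1L)
      feats[, , (s - 1L) * 7L + cls] <- as.integer(round(cnt))
    }
  }
  new("FeatureStack", features = feats, scales = bifs@scales,
      epsilon = bifs@epsilon, window = window)
}

#' One-call per-pixel features
#'
#' Convenience wrapper: jets, BIF classification and local histograms in
#' one step with the standard defaults.
#'
#' @inheritParams bifStack
#' @inheritParams featureStack
#' @return a \linkS4class{FeatureStack}.
#' @export
pixelFeatures <- function(img, scales = 0.7 * c(1, 2, 4, 8),
                          epsilon = 0.11, window = 25L) {
  featureStack(bifStack(img, scales, epsilon), window)
}

#' Flatten a feature stack to a table
#'
#' @param fs a \linkS4class{FeatureStack}.
#' @return data.frame with columns row, col and f1..fF.
#' @export
featuresAsTable <- function(fs) {
  d <- dim(fs@features)
  m <- matrix(fs@features, d[1L] * d[2L], d[3L])
  colnames(m) <- paste0("f", seq_len(d[3L]))
  cbind(data.frame(row = rep(seq_len(d[1L]), d[2L]),
                   col = rep(seq_len(d[2L]), each = d[1L])),
        as.data.frame(m))
}

# feature matrix (pixels x F) from a stack, for classifier use
featureMatrix <- function(fs) {
  d <- dim(fs@features)
  m <- matrix(as.numeric(fs@features), d[1L] * d[2L], d[3L])
  colnames(m) <- paste0("f", seq_len(d[3L]))
  m
}

# configuration fingerprint shared by features and classifier
featureFingerprint <- function(scales, epsilon, window) {
  digest::digest(list(scales = as.numeric(scales),
                      epsilon = as.numeric(epsilon),
                      window = as.integer(window)), algo = "sha1")
}
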