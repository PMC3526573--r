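## Pixel-level agreement between predicted and reference masks.

#' Pixel confusion counts between two binary masks
#'
#' @param pred,ref binary (0/1) matrices of identical shape; reference is
#'   the expert annotation.
#' @return a \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(pred, ref) {
  p <- as.matrix(pred); r <- as.matrix(ref)
  if (!identical(dim(p), dim(r)))
    stop(sprintf("mask shapes differ: %dx%d vs %dx%d",
                 nrow(p), ncol(p), nrow(r), ncol(r)))
  if (!all(p %in% c(0, 1)) || !all(r %in% c(0, 1)))
    stop("masks must be binary 0/1")
  new("ConfusionCounts",
      tp = as.numeric(sum(p == 1 & r == 1)),
      fp = as.numeric(sum(p == 1 & r == 0)),
      fn = as.numeric(sum(p == 0 & r == 1)),
      tn = as.numeric(sum(p == 0 & r == 0)))
}

#' @rdname fScore
#' @export
setMethod("fScore", "ConfusionCounts", function(x, ...) {
  denom <- 2 * x@tp + x@fp + x@fn
  if (denom == 0)
    stop("F-score undefined: no positive pixels in either mask")
  2 * x@tp / denom
})

#' @rdname fScore
#' @param fp,fn false positive and false negative counts.
#' @export
setMethod("fScore", "numeric", function(x, fp, fn, ...) {
  fScore(new("ConfusionCounts", tp = x, fp = fp, fn = fn, tn = 0))
})

#' Confluency-error and F-score report over image pairs
#'
#' For each (predicted, reference) mask pair, computes the pixel F-score
#' and the signed confluency error (estimated minus reference). Summary
#' statistics follow the bias/RMSE decomposition: bias is the mean error
#' with a Student-t 95% confidence interval, RMSE the root mean squared
#' error, and precision the scatter component
#' \code{sqrt(RMSE^2 - bias^2)}.
#'
#' @param predList,refList lists of binary masks (or
#'   \linkS4class{ColonyLabelMap}s) in matching order.
#' @param ids optional character ids for the report rows.
#' @param conf confidence level for the bias interval (default 0.95).
#' @return an \linkS4class{EvaluationReport}.
#' @export
confluencyReport <- function(predList, refList, ids = NULL, conf = 0.95) {
  stopifnot(length(predList) == length(refList), length(predList) >= 1L)
  if (is.null(ids)) ids <- sprintf("pair%03d", seq_along(predList))
  asMask <- function(x) if (is(x, "ColonyLabelMap")) colonyMask(x) else x
  f <- conf_p <- conf_r <- numeric(length(predList))
  for (i in seq_along(predList)) {
    p <- asMask(predList[[i]]); r <- asMask(refList[[i]])
    cc <- confusionCounts(p, r)
    f[i] <- fScore(cc)
    conf_p[i] <- sum(p == 1) / length(p)
    conf_r[i] <- sum(r == 1) / length(r)
  }
  delta <- conf_p - conf_r
  n <- length(delta)
  bias <- mean(delta)
  rmse <- sqrt(mean(delta^2))
  prec2 <- rmse^2 - bias^2
  precision <- sqrt(max(prec2, 0))
  ci <- c(NA_real_, NA_real_)
  if (n >= 2L) {
    se <- stats::sd(delta) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1L)
    ci <- bias + c(-1, 1) * tq * se
  } else {
    warning("fewer than 2 image pairs: bias CI omitted")
  }
  new("EvaluationReport",
      perImage = data.frame(id = ids, fscore = f, confPred = conf_p,
                            confRef = conf_r, delta = delta),
      meanF = mean(f), sdF = if (n >= 2L) stats::sd(f) else NA_real_,
      bias = bias, biasCI = ci, rmse = rmse, precisionStat = precision)
}

#' Colour-coded agreement overlay
#'
#' Renders the pixel agreement between a prediction and a reference as an
#' RGB array: true positives yellow, true negatives black, false
#' positives green, false negatives red.
#'
#' @param pred,ref binary masks of identical shape.
#' @return H x W x 3 numeric array on [0, 1].
#' @export
agreementOverlay <- function(pred, ref) {
  p <- as.matrix(pred); r <- as.matrix(ref)
  if (!identical(dim(p), dim(r))) stop("mask shapes differ")
  out <- array(0, dim = c(nrow(p), ncol(p), 3L))
  tp <- p == 1 & r == 1
  fp <- p == 1 & r == 0
  fn <- p == 0 & r == 1
  red <- matrix(0, nrow(p), ncol(p)); green <- red
  red[tp] <- 1; green[tp] <- 1   # yellow
  green[fp] <- 1                 # green
  red[fn] <- 1                   # red
  out[, , 1L] <- red
  out[, , 2L] <- green
  out
}
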