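## Morphological cleanup of raw classifier masks and colony metrics.
##
## Connected components are labelled with a run-based union-find pass so
## that objects can use 8-connectivity while holes use 4-connectivity
## (the complementary pair that avoids topological paradoxes).

#' Label connected components of a binary mask
#'
#' Two-pass row-run labelling with union-find. Components of the value-1
#' pixels are numbered 1..K in raster order of first appearance.
#'
#' @param mask integer/logical matrix; non-zero is foreground.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background).
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  H <- nrow(m); W <- ncol(m)
  slack <- if (connectivity == 8L) 1L else 0L
  parent <- integer(0)
  ufFind <- function(i) {  # union-find with path halving
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  labels <- matrix(0L, H, W)
  prevRuns <- NULL  # matrix: start, end, label
  for (r in seq_len(H)) {
    v <- m[r, ]
    dd <- diff(c(0L, v, 0L))
    starts <- which(dd == 1L)
    ends <- which(dd == -1L) - 1L
    if (length(starts) == 0L) { prevRuns <- NULL; next }
    curLab <- integer(length(starts))
    for (k in seq_along(starts)) {
      lab <- 0L
      if (!is.null(prevRuns)) {
        hits <- which(prevRuns[, 2L] >= starts[k] - slack &
                      prevRuns[, 1L] <= ends[k] + slack)
        for (h in hits) {
          root <- ufFind(prevRuns[h, 3L])
          if (lab == 0L) lab <- root
          else if (root != lab) {
            keep <- min(root, lab); drop <- max(root, lab)
            parent[drop] <- keep
            lab <- keep
          }
        }
      }
      if (lab == 0L) {
        parent <- c(parent, length(parent) + 1L)
        lab <- length(parent)
      }
      curLab[k] <- lab
      labels[r, starts[k]:ends[k]] <- lab
    }
    prevRuns <- cbind(starts, ends, curLab)
  }
  if (length(parent) == 0L) return(labels)
  roots <- vapply(seq_along(parent), function(i) ufFind(i),
                  integer(1))
  # renumber roots 1..K in raster order of first appearance
  pos <- which(labels > 0L)
  rr <- ((pos - 1L) %% H) + 1L
  cc <- ((pos - 1L) %/% H) + 1L
  o <- order(rr, cc)
  remap <- integer(length(parent))
  nxt <- 0L
  for (i in o) {
    root <- roots[labels[pos[i]]]
    if (remap[root] == 0L) { nxt <- nxt + 1L; remap[root] <- nxt }
  }
  labels[pos] <- remap[roots[labels[pos]]]
  labels
}

#' Clean a raw binary colony map
#'
#' Applies the two size filters in order: connected objects smaller than
#' \code{minObject} pixels (strict inequality) are discarded as detection
#' noise, then enclosed holes smaller than \code{minHoleFill} pixels are
#' filled. Objects use 8-connectivity, holes 4-connectivity; a hole is a
#' background component not touching the image border, measured after
#' object removal. Components of the result are labelled 1..K.
#'
#' @param rawMask binary (0/1) matrix from \code{\link{predictMask}}.
#' @param minObject objects below this pixel count are removed
#'   (default 4000).
#' @param minHoleFill holes below this pixel count are filled
#'   (default 6000).
#' @param calibration area per pixel in um^2 carried into the result.
#' @return a \linkS4class{ColonyLabelMap}.
#' @export
cleanupMask <- function(rawMask, minObject = 4000L, minHoleFill = 6000L,
                        calibration = 2.86) {
  m <- as.matrix(rawMask)
  if (!all(m %in% c(0, 1)))
    stop("cleanup expects a binary 0/1 mask")
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  ## 1. discard small objects (8-connectivity)
  lab <- labelComponents(m, 8L)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    small <- which(sizes < minObject)
    if (length(small)) m[lab %in% small] <- 0L
  }
  ## 2. fill small enclosed holes (4-connectivity on the complement)
  bg <- labelComponents(1L - m, 4L)
  if (max(bg) > 0L) {
    border <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
    border <- border[border > 0L]
    sizes <- tabulate(bg[bg > 0L], nbins = max(bg))
    holes <- setdiff(which(sizes < minHoleFill), border)
    if (length(holes)) m[bg %in% holes] <- 1L
  }
  lab <- labelComponents(m, 8L)
  areas <- if (max(lab) > 0L) tabulate(lab[lab > 0L], nbins = max(lab))
           else integer(0)
  new("ColonyLabelMap", mask = m, labels = lab,
      areasPx = as.integer(areas), calibration = calibration)
}

#' Colony metrics from a labelled map
#'
#' Total area is positive pixels times the calibration factor; confluency
#' is positives over all pixels; mean area is total over colony count
#' (reported 0 with \code{meanDefined = FALSE} when nothing was
#' detected). Areas are in mm^2.
#'
#' @param map a \linkS4class{ColonyLabelMap}.
#' @return a \linkS4class{ColonyMetrics}.
#' @export
colonyMetrics <- function(map) {
  stopifnot(is(map, "ColonyLabelMap"))
  npos <- sum(map@mask == 1L)
  k <- length(map@areasPx)
  totalMm2 <- npos * map@calibration / 1e6  # um^2 -> mm^2
  new("ColonyMetrics",
      nColonies = k,
      totalArea = totalMm2,
      meanArea = if (k > 0L) totalMm2 / k else 0,
      confluency = npos / length(map@mask),
      meanDefined = k > 0L)
}

#' Per-colony table
#'
#' @param map a \linkS4class{ColonyLabelMap}.
#' @return data.frame with columns id, area_px, area_mm2, centroid_row,
#'   centroid_col.
#' @export
colonyTable <- function(map) {
  stopifnot(is(map, "ColonyLabelMap"))
  k <- length(map@areasPx)
  if (k == 0L)
    return(data.frame(id = integer(0), area_px = integer(0),
                      area_mm2 = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0)))
  pos <- which(map@labels > 0L)
  ids <- map@labels[pos]
  rr <- ((pos - 1L) %% nrow(map@labels)) + 1L
  cc <- ((pos - 1L) %/% nrow(map@labels)) + 1L
  data.frame(
    id = seq_len(k),
    area_px = map@areasPx,
    area_mm2 = map@areasPx * map@calibration / 1e6,
    centroid_row = as.numeric(tapply(rr, ids, mean)),
    centroid_col = as.numeric(tapply(cc, ids, mean)))
}
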