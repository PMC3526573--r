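## Procedural generator of phase-contrast-like two-texture images with
## ground-truth colony masks. Colony interiors carry dense fine-grained
## granular texture (small tightly packed cells); the background carries
## sparse elongated strokes emulating a fibroblast feeder layer; a smooth
## illumination field, additive noise and a bright rim halo complete the
## phenomenological model.

#' Generator configuration
#'
#' All arguments have defaults describing the standard study conditions:
#' 500 x 500 frames with 1-6 colonies of 40-150 px radius and irregular
#' outlines over a sparse stroke background.
#'
#' @param size image (rows, cols) in pixels.
#' @param nColonies inclusive range of colony counts.
#' @param radiusRange colony radius range (px).
#' @param boundaryIrregularity relative radial perturbation amplitude of
#'   colony outlines (0 gives perfect discs).
#' @param colonyContrast SD of the granular in-colony texture.
#' @param colonyBlobDensity stamped micro-blobs per colony pixel.
#' @param colonyBlobSize blob radius range (px).
#' @param strokeDensity strokes per image pixel.
#' @param strokeLength,strokeWidth stroke geometry ranges (px).
#' @param strokeContrast stroke darkening amplitude.
#' @param illuminationAmplitude amplitude of the smooth illumination
#'   gradient.
#' @param noiseSd SD of additive Gaussian pixel noise.
#' @param haloStrength brightening of the thin band outside colony rims.
#' @param calibration um^2 per pixel attached to generated images.
#' @param seed integer seed; fixes the full sample path.
#' @return a \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(size = c(500L, 500L), nColonies = c(1L, 6L),
                            radiusRange = c(40, 150),
                            boundaryIrregularity = 0.15,
                            colonyContrast = 0.18,
                            colonyBlobDensity = 0.01,
                            colonyBlobSize = c(2, 5),
                            strokeDensity = 3e-4,
                            strokeLength = c(30, 80),
                            strokeWidth = c(3, 6),
                            strokeContrast = 0.12,
                            illuminationAmplitude = 0.08,
                            noiseSd = 0.03,
                            haloStrength = 0.10,
                            calibration = 2.86,
                            seed = 1L) {
  if (length(nColonies) == 1L) nColonies <- rep(nColonies, 2L)
  new("GeneratorConfig",
      size = as.integer(size), nColonies = as.integer(nColonies),
      radiusRange = radiusRange,
      boundaryIrregularity = boundaryIrregularity,
      colonyContrast = colonyContrast,
      colonyBlobDensity = colonyBlobDensity,
      colonyBlobSize = colonyBlobSize,
      strokeDensity = strokeDensity, strokeLength = strokeLength,
      strokeWidth = strokeWidth, strokeContrast = strokeContrast,
      illuminationAmplitude = illuminationAmplitude, noiseSd = noiseSd,
      haloStrength = haloStrength, calibration = calibration,
      seed = as.integer(seed))
}

# rasterise one colony: disc with Fourier-perturbed radius
rasteriseColony <- function(H, W, cx, cy, r0, irregularity) {
  nh <- 5L
  a <- stats::rnorm(nh); b <- stats::rnorm(nh)
  norm <- sum(abs(a)) + sum(abs(b))
  pad <- ceiling(r0 * (1 + irregularity)) + 1L
  rows <- max(1L, floor(cy - pad)):min(H, ceiling(cy + pad))
  cols <- max(1L, floor(cx - pad)):min(W, ceiling(cx + pad))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  d <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  pert <- 0
  if (irregularity > 0 && norm > 0) {
    pert <- matrix(0, length(rows), length(cols))
    for (k in seq_len(nh))
      pert <- pert + a[k] * cos(k * th) + b[k] * sin(k * th)
    pert <- pert / norm  # |pert| <= 1
  }
  inside <- d <= r0 * (1 + irregularity * pert)
  list(rows = rows, cols = cols, inside = inside)
}

# paint a dark stroke (capsule) with a faint bright border
paintStroke <- function(img, cx, cy, phi, len, width, amp) {
  hx <- cos(phi) * len / 2; hy <- sin(phi) * len / 2
  pad <- ceiling(width / 2 + 1.5)
  x1 <- cx - hx; y1 <- cy - hy; x2 <- cx + hx; y2 <- cy + hy
  rows <- max(1L, floor(min(y1, y2) - pad)):min(nrow(img),
                                                ceiling(max(y1, y2) + pad))
  cols <- max(1L, floor(min(x1, x2) - pad)):min(ncol(img),
                                                ceiling(max(x1, x2) + pad))
  if (!length(rows) || !length(cols)) return(img)
  py <- outer(rows, rep(1, length(cols)))
  px <- outer(rep(1, length(rows)), cols)
  vx <- x2 - x1; vy <- y2 - y1
  tproj <- ((px - x1) * vx + (py - y1) * vy) / (vx^2 + vy^2)
  tproj <- pmin(pmax(tproj, 0), 1)
  d <- sqrt((px - (x1 + tproj * vx))^2 + (py - (y1 + tproj * vy))^2)
  core <- d <= width / 2
  rim <- d > width / 2 & d <= width / 2 + 1
  patch <- img[rows, cols]
  patch[core] <- patch[core] - amp
  patch[rim] <- patch[rim] + 0.4 * amp
  img[rows, cols] <- patch
  img
}

#' Generate a synthetic two-texture image with ground truth
#'
#' Draws colony outlines, composes the two textures, illumination
#' gradient, rim halo and pixel noise, and returns the image together
#' with the exact rasterised mask and a per-colony table. The whole
#' sample path is a deterministic function of the config seed.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return list with elements \code{image} (\linkS4class{GrayImage}),
#'   \code{mask} (integer 0/1 matrix) and \code{colonies} (data.frame:
#'   id, center_row, center_col, radius_px, area_px).
#' @export
generateColonyImage <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  set.seed(config@seed)
  H <- config@size[1L]; W <- config@size[2L]
  mask <- matrix(0L, H, W)

  ## colony geometry
  n <- if (config@nColonies[1L] == config@nColonies[2L]) config@nColonies[1L]
       else sample(config@nColonies[1L]:config@nColonies[2L], 1L)
  tab <- data.frame(id = integer(0), center_row = numeric(0),
                    center_col = numeric(0), radius_px = numeric(0),
                    area_px = integer(0))
  for (i in seq_len(n)) {
    r0 <- stats::runif(1, config@radiusRange[1L], config@radiusRange[2L])
    margin <- r0 * (1 + config@boundaryIrregularity)
    cy <- stats::runif(1, 1 + margin, H - margin)
    cx <- stats::runif(1, 1 + margin, W - margin)
    col <- rasteriseColony(H, W, cx, cy, r0, config@boundaryIrregularity)
    sub <- mask[col$rows, col$cols]
    sub[col$inside] <- 1L
    mask[col$rows, col$cols] <- sub
    tab <- rbind(tab, data.frame(id = i, center_row = cy, center_col = cx,
                                 radius_px = r0,
                                 area_px = sum(col$inside)))
  }

  ## illumination field: tilted plane plus gentle radial bowl
  yy <- (seq_len(H) - (H + 1) / 2) / H
  xx <- (seq_len(W) - (W + 1) / 2) / W
  phi <- stats::runif(1, 0, 2 * pi)
  plane <- outer(yy, rep(1, W)) * sin(phi) + outer(rep(1, H), xx) * cos(phi)
  bowl <- outer(yy^2, rep(1, W)) + outer(rep(1, H), xx^2)
  img <- 0.5 + config@illuminationAmplitude * (plane - 0.7 * bowl)

  ## background: sparse elongated strokes (painted everywhere, colony
  ## texture overwrites the interior below)
  strokes <- matrix(0, H, W)
  nStrokes <- stats::rpois(1, config@strokeDensity * H * W)
  for (s in seq_len(nStrokes)) {
    strokes <- paintStroke(
      strokes,
      cx = stats::runif(1, 1, W), cy = stats::runif(1, 1, H),
      phi = stats::runif(1, 0, pi),
      len = stats::runif(1, config@strokeLength[1L], config@strokeLength[2L]),
      width = stats::runif(1, config@strokeWidth[1L], config@strokeWidth[2L]),
      amp = config@strokeContrast * stats::runif(1, 0.6, 1))
  }
  img[mask == 0L] <- img[mask == 0L] + strokes[mask == 0L]

  ## colony interior: fine granular speckle plus stamped dark micro-blobs
  if (any(mask == 1L)) {
    speck <- matrix(stats::rnorm(H * W), H, W)
    k <- gaussianKernel(0.8, 0L)
    speck <- convolve1d(convolve1d(speck, k, 2L), k, 1L)
    speck <- speck / stats::sd(speck) * config@colonyContrast
    img[mask == 1L] <- img[mask == 1L] + speck[mask == 1L]
    nBlobs <- stats::rpois(1, config@colonyBlobDensity * sum(mask))
    inIdx <- which(mask == 1L)
    if (nBlobs > 0 && length(inIdx) > 0) {
      centers <- sample(inIdx, nBlobs, replace = TRUE)
      depth <- 1.2 * config@colonyContrast
      for (b in centers) {
        br <- stats::runif(1, config@colonyBlobSize[1L],
                           config@colonyBlobSize[2L]) / 2
        cy <- ((b - 1L) %% H) + 1L
        cx <- ((b - 1L) %/% H) + 1L
        rows <- max(1L, cy - ceiling(br)):min(H, cy + ceiling(br))
        cols <- max(1L, cx - ceiling(br)):min(W, cx + ceiling(br))
        dd <- outer((rows - cy)^2, rep(1, length(cols))) +
              outer(rep(1, length(rows)), (cols - cx)^2)
        hit <- dd <= br^2
        patch <- img[rows, cols]
        patch[hit] <- patch[hit] - depth
        img[rows, cols] <- patch
      }
    }
  }

  ## bright halo in a 3 px band outside colony rims
  if (config@haloStrength > 0 && any(mask == 1L)) {
    ones7 <- rep(1, 7)
    near <- convolve1d(convolve1d(matrix(as.numeric(mask), H, W), ones7, 2L),
                       ones7, 1L)
    ring <- near > 0 & mask == 0L
    img[ring] <- img[ring] + config@haloStrength
  }

  ## pixel noise, clip to displayable range
  img <- img + matrix(stats::rnorm(H * W, sd = config@noiseSd), H, W)
  img <- pmin(pmax(img, 0), 1)

  list(image = new("GrayImage", pixels = img,
                   calibration = config@calibration, profile = "synthetic"),
       mask = mask, colonies = tab)
}

#' Build a training set from generated images
#'
#' Generates one image per config, computes BIF histogram features and
#' samples labelled pixels, balanced across the two classes by default.
#'
#' @param configs list of \linkS4class{GeneratorConfig} objects (or a
#'   single config).
#' @param pixelsPerImage labelled pixels sampled per image.
#' @param balance enforce a 1:1 class balance per image.
#' @param scales,epsilon,window feature configuration.
#' @param samplingSeed seed for the pixel sampling step.
#' @return a \linkS4class{TrainingSet}.
#' @export
makeTrainingSet <- function(configs, pixelsPerImage = 20000L,
                            balance = TRUE,
                            scales = 0.7 * c(1, 2, 4, 8), epsilon = 0.11,
                            window = 25L, samplingSeed = 1L) {
  if (is(configs, "GeneratorConfig")) configs <- list(configs)
  stopifnot(length(configs) >= 1L)
  featL <- list(); maskL <- list(); ids <- character(length(configs))
  for (i in seq_along(configs)) {
    sim <- generateColonyImage(configs[[i]])
    featL[[i]] <- pixelFeatures(sim$image, scales, epsilon, window)
    maskL[[i]] <- sim$mask
    ids[i] <- sprintf("sim%05d", configs[[i]]@seed)
  }
  buildTrainingSet(featL, maskL, pixelsPerImage = pixelsPerImage,
                   balance = balance, imageIds = ids, seed = samplingSeed)
}

#' Write a batch of simulated images, masks and truth table
#'
#' @param config base \linkS4class{GeneratorConfig}; image i uses seed
#'   \code{config@seed + i - 1}.
#' @param n number of images.
#' @param dir output directory (created if needed).
#' @return data.frame of per-image truth (id, n_colonies, confluency),
#'   invisibly; files image_###.png, mask_###.png and truth.csv appear in
#'   \code{dir}.
#' @export
simulateBatch <- function(config, n, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg@seed <- config@seed + i - 1L
    sim <- generateColonyImage(cfg)
    id <- sprintf("%03d", i)
    saveImage(sim$image, file.path(dir, paste0("image_", id, ".png")))
    saveImage(sim$mask, file.path(dir, paste0("mask_", id, ".png")))
    rows[[i]] <- data.frame(id = id, seed = cfg@seed,
                            n_colonies = nrow(sim$colonies),
                            confluency = mean(sim$mask))
  }
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}
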