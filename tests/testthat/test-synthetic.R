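test_that("the generator honours colony counts and analytic areas", {
  # no colonies: empty mask, zero confluency
  sim0 <- generateColonyImage(smallConfig(seed = 4, nColonies = c(0L, 0L)))
  expect_true(all(sim0$mask == 0L))
  expect_identical(nrow(sim0$colonies), 0L)

  # one unperturbed disc of radius 100 in 500 x 500: area ~ pi r^2
  cfg <- generatorConfig(seed = 9, nColonies = c(1L, 1L),
                         radiusRange = c(100, 100),
                         boundaryIrregularity = 0)
  sim1 <- generateColonyImage(cfg)
  trueConf <- pi * 100^2 / 500^2
  expect_lt(abs(mean(sim1$mask) - trueConf) / trueConf, 0.01)
  expect_identical(sum(sim1$mask), sim1$colonies$area_px)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- smallConfig(seed = 123)
  a <- generateColonyImage(cfg)
  b <- generateColonyImage(cfg)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$mask, b$mask)
  expect_identical(a$colonies, b$colonies)
  c <- generateColonyImage(smallConfig(seed = 124))
  expect_false(identical(pixels(a$image), pixels(c$image)))
})

test_that("impossible geometry is rejected at construction", {
  expect_error(generatorConfig(size = c(100L, 100L),
                               radiusRange = c(40, 80)), "fit")
})

test_that("training-set assembly keeps its bookkeeping promises", {
  cfgs <- lapply(1:2, smallConfig)
  ts <- makeTrainingSet(cfgs, pixelsPerImage = 1000L,
                        scales = smallFeatureArgs$scales,
                        epsilon = smallFeatureArgs$epsilon,
                        window = smallFeatureArgs$window)
  expect_identical(nrow(ts@features), 2000L)
  expect_equal(mean(ts@labels), 0.5)  # balanced 1:1
  expect_identical(ncol(ts@features), 21L)  # 7 bins x 3 scales
  expect_setequal(unique(ts@provenance$image), c("sim00001", "sim00002"))
  # provenance points back at in-range pixels
  expect_true(all(ts@provenance$row >= 1 & ts@provenance$row <= 128))
})

test_that("texture contrast controls class separability", {
  mkF <- function(contrast, stroke, halo) {
    cfgs <- lapply(200:202, function(s)
      smallConfig(seed = s, colonyContrast = contrast,
                  strokeContrast = stroke, haloStrength = halo))
    ts <- makeTrainingSet(cfgs, pixelsPerImage = 2000L,
                          scales = smallFeatureArgs$scales,
                          epsilon = smallFeatureArgs$epsilon,
                          window = smallFeatureArgs$window)
    model <- trainColonyClassifier(ts, seed = 5)
    fs <- numeric(2)
    for (i in 1:2) {
      sim <- generateColonyImage(
        smallConfig(seed = 210 + i, colonyContrast = contrast,
                    strokeContrast = stroke, haloStrength = halo))
      pred <- predictMask(model, pixelFeatures(
        sim$image, smallFeatureArgs$scales, smallFeatureArgs$epsilon,
        smallFeatureArgs$window))
      fs[i] <- fScore(confusionCounts(pred, sim$mask))
    }
    mean(fs)
  }
  fDefault <- mkF(0.18, 0.12, 0.10)
  fZero <- mkF(0, 0, 0)
  expect_gte(fDefault, 0.9)
  expect_lt(fZero, 0.75)  # toward chance once the textures vanish
  expect_lt(fZero, fDefault)
})

test_that("simulated batches land on disk with a truth table", {
  dir <- withr::local_tempdir()
  truth <- simulateBatch(smallConfig(seed = 300), n = 3, dir = dir)
  expect_identical(nrow(truth), 3L)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_length(list.files(dir, pattern = "^image_"), 3L)
  expect_length(list.files(dir, pattern = "^mask_"), 3L)
  m <- loadMask(file.path(dir, "mask_001.png"))
  expect_equal(mean(m), truth$confluency[1])
})
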