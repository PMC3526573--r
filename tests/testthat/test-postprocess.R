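test_that("component labelling matches the flood-fill oracle", {
  set.seed(21)
  for (rep in 1:5) {
    mask <- matrix(rbinom(30 * 25, 1, 0.4), 30, 25)
    for (conn in c(4L, 8L)) {
      got <- labelComponents(mask, conn)
      ref <- bruteLabel(mask, conn)
      expect_identical(got, ref)
    }
  }
})

test_that("4-connectivity labelling agrees with EBImage::bwlabel", {
  skip_if_not_installed("EBImage")
  set.seed(33)
  mask <- matrix(rbinom(40 * 40, 1, 0.45), 40, 40)
  got <- labelComponents(mask, 4L)
  ref <- EBImage::bwlabel(mask)
  # same partition (labelling order may differ)
  expect_identical(max(got), as.integer(max(ref)))
  key <- paste(got[mask == 1], ref[mask == 1])
  expect_identical(length(unique(key)), max(got))
})

test_that("objects below the size threshold are removed (strict <)", {
  mask <- matrix(0L, 120, 120)
  mask[11:60, 11:90] <- 1L  # 50 x 80 = 4000 px: survives
  keep <- cleanupMask(mask)
  expect_identical(nColonies(keep), 1L)
  expect_identical(colonyAreas(keep), 4000L)

  mask[11, 11] <- 0L        # 3999 px: removed
  gone <- cleanupMask(mask)
  expect_identical(nColonies(gone), 0L)
  expect_true(all(colonyMask(gone) == 0L))
})

test_that("small enclosed holes are filled, large ones kept", {
  # 5000 px object enclosing a 100 px hole -> filled to 5100
  mask <- matrix(0L, 200, 200)
  mask[50:109, 50:134] <- 1L            # 60 x 85 = 5100
  mask[70:79, 70:79] <- 0L              # 10 x 10 hole -> 5000 px object
  out <- cleanupMask(mask, minObject = 4000L, minHoleFill = 6000L)
  expect_identical(nColonies(out), 1L)
  expect_identical(colonyAreas(out), 5100L)
  expect_true(all(colonyMask(out)[70:79, 70:79] == 1L))

  # hole at the threshold size is not filled (strict <)
  big <- matrix(0L, 300, 300)
  big[11:290, 11:290] <- 1L
  big[101:200, 101:160] <- 0L  # 100 x 60 = 6000 px hole
  out2 <- cleanupMask(big)
  expect_true(all(colonyMask(out2)[101:200, 101:160] == 0L))
  big[101:200, 101:160] <- 0L
  big[200, 101:160] <- 1L      # shrink hole to 5940 < 6000 -> filled
  out3 <- cleanupMask(big)
  expect_true(all(colonyMask(out3)[101:199, 101:160] == 1L))
})

test_that("background touching the border is never treated as a hole", {
  mask <- matrix(1L, 100, 100)
  mask[1:50, 40:60] <- 0L  # notch open to the border
  out <- cleanupMask(mask)
  expect_true(all(colonyMask(out)[1:50, 40:60] == 0L))
})

test_that("cleanup is idempotent and validates input", {
  empty <- matrix(0L, 64, 64)
  out <- cleanupMask(empty)
  expect_true(all(colonyMask(out) == 0L))
  expect_identical(nColonies(out), 0L)

  set.seed(14)
  model <- smallModel()
  sim <- generateColonyImage(smallConfig(seed = 70))
  raw <- predictMask(model, smallFeatures(sim$image))
  once <- cleanupMask(raw, 200L, 300L)
  twice <- cleanupMask(colonyMask(once), 200L, 300L)
  expect_identical(colonyMask(twice), colonyMask(once))
  expect_identical(colonyLabels(twice), colonyLabels(once))

  expect_error(cleanupMask(matrix(c(0, 1, 2, 1), 2, 2)), "binary")
})

test_that("metrics follow the calibration and conservation identities", {
  mask <- matrix(0L, 200, 200)
  mask[1:20, 1:50] <- 1L  # 1000 px
  map <- cleanupMask(mask, minObject = 1L, minHoleFill = 1L,
                     calibration = 2.86)
  m <- colonyMetrics(map)
  expect_equal(m@totalArea, 2.86e-3)        # 2860 um^2 in mm^2
  expect_equal(confluency(m), 1000 / 40000)
  expect_equal(confluency(m) * 200 * 200, sum(colonyAreas(map)))

  zero <- colonyMetrics(cleanupMask(matrix(0L, 10, 10)))
  expect_identical(nColonies(zero), 0L)
  expect_identical(confluency(zero), 0)
  expect_false(zero@meanDefined)
})

test_that("per-colony tables report areas and centroids", {
  mask <- matrix(0L, 100, 100)
  mask[11:30, 11:30] <- 1L   # 400 px, centroid (20.5, 20.5)
  mask[61:90, 51:70] <- 1L   # 600 px
  map <- cleanupMask(mask, minObject = 1L, minHoleFill = 1L,
                     calibration = 10)
  tab <- colonyTable(map)
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$area_px, c(400L, 600L))
  i <- which(tab$area_px == 400L)
  expect_equal(tab$centroid_row[i], 20.5)
  expect_equal(tab$centroid_col[i], 20.5)
  expect_equal(tab$area_mm2, tab$area_px * 10 / 1e6)
})
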