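test_that("jets of simple analytic images behave as expected", {
  # constant image: zero derivatives, c00 equals the value
  jc <- jet(matrix(5, 32, 32), 1.4)
  expect_equal(jc@c00, matrix(5, 32, 32), tolerance = 1e-12)
  expect_lt(max(abs(jc@c10)), 1e-12)
  expect_lt(max(abs(jc@c20)), 1e-12)

  # unit ramp along x: scale-normalised gradient c10 ~ sigma, second
  # derivatives vanish away from borders
  ramp <- outer(rep(1, 48), 1:48)
  for (s in c(0.7, 1.4, 2.8)) {
    j <- jet(ramp, s)
    mid <- j@c10[20:28, 20:28]
    expect_equal(mean(mid), s, tolerance = 1e-2)
    expect_lt(max(abs(j@c20[20:28, 20:28])), 1e-8)
    expect_lt(max(abs(j@c11[20:28, 20:28])), 1e-8)
    expect_lt(max(abs(j@c01[20:28, 20:28])), 1e-8)
  }
  expect_error(jet(ramp, 0), "positive")
  expect_error(jet(ramp, -1), "positive")
})

test_that("separable filtering matches the direct-convolution oracle", {
  set.seed(11)
  img <- matrix(runif(32 * 32), 32, 32)
  for (s in c(0.7, 2.1)) {
    j <- jet(img, s)
    pairs <- list(c00 = c(0, 0), c10 = c(1, 0), c01 = c(0, 1),
                  c20 = c(2, 0), c11 = c(1, 1), c02 = c(0, 2))
    for (nm in names(pairs)) {
      o <- pairs[[nm]]
      ref <- s^(o[1] + o[2]) * bruteConv2d(img, outerKernel(s, o[1], o[2]))
      got <- slot(j, nm)
      expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-8)
    }
  }
})

test_that("classification recovers the canonical local symmetries", {
  # constant positive image: flat everywhere
  labs <- classifyBIF(jet(matrix(3, 24, 24), 1.4), 0.11)
  expect_true(all(labs == 1L))

  # ramp: slope wherever the flat score eps*c00 stays below 2*sigma,
  # i.e. columns < 2*2.8/0.11 ~ 51 for a unit-slope ramp at sigma 2.8
  ramp <- outer(rep(1, 48), 1:48) * 0.01
  labs <- classifyBIF(jet(ramp, 2.8), 0.11)
  expect_true(all(labs[20:28, 20:28] == 2L))

  # isolated dark disc on a brighter background: dark blob at the centre
  img <- matrix(0.6, 41, 41)
  dd <- outer((1:41 - 21)^2, rep(1, 41)) + outer(rep(1, 41), (1:41 - 21)^2)
  img[dd <= 16] <- 0.1
  labs <- classifyBIF(jet(img, 2.8), 0.11)
  expect_identical(labs[21, 21], 3L)
  # the same disc in negative: light blob at the centre
  labs2 <- classifyBIF(jet(0.7 - img, 2.8), 0.11)
  expect_identical(labs2[21, 21], 4L)

  expect_error(classifyBIF(jet(ramp, 1.4), 0), "positive")
})

test_that("labels are invariant to global intensity rescaling", {
  set.seed(3)
  img <- matrix(runif(40 * 40), 40, 40)
  for (s in c(0.7, 2.8)) {
    l1 <- classifyBIF(jet(img, s), 0.11)
    l2 <- classifyBIF(jet(7.3 * img, s), 0.11)
    expect_identical(l1, l2)
    expect_true(all(l1 %in% 1:7))
  }
})

test_that("bifStack produces one plane per scale with defaults", {
  stk <- bifStack(matrix(2, 20, 20))
  expect_identical(dim(bifLabels(stk)), c(20L, 20L, 4L))
  expect_equal(bifScales(stk), 0.7 * c(1, 2, 4, 8))
  expect_true(all(bifLabels(stk) == 1L))  # constant -> all flat

  one <- bifStack(matrix(2, 20, 20), scales = 1.4)
  expect_identical(dim(bifLabels(one))[3], 1L)
  expect_error(bifStack(matrix(2, 20, 20), scales = numeric(0)), "scale")
})

test_that("feature vectors are concatenated window histograms", {
  # constant image: every count lands in the flat bin
  fs <- featureStack(bifStack(matrix(1, 40, 40)), window = 25L)
  f <- featureArray(fs)
  expect_identical(dim(f)[3], 28L)
  v <- f[20, 20, ]
  expect_equal(v[seq(1, 28, by = 7)], rep(625L, 4))  # flat bin per scale
  expect_equal(sum(v), 2500L)
  expect_true(all(v[-seq(1, 28, by = 7)] == 0L))

  # window 1: one-hot histogram of the pixel's own label
  set.seed(5)
  img <- matrix(runif(30 * 30), 30, 30)
  stk <- bifStack(img, scales = c(0.7, 1.4))
  f1 <- featureArray(featureStack(stk, window = 1L))
  for (p in list(c(7, 9), c(15, 22))) {
    for (s in 1:2) {
      hist <- f1[p[1], p[2], (s - 1) * 7 + 1:7]
      expect_equal(sum(hist), 1L)
      expect_equal(which(hist == 1L),
                   as.integer(bifLabels(stk)[p[1], p[2], s]))
    }
  }
  expect_error(featureStack(stk, window = 4L), "odd")
})

test_that("histogram bins conserve the window pixel count everywhere", {
  set.seed(9)
  img <- matrix(runif(35 * 31), 35, 31)
  fs <- featureStack(bifStack(img, scales = c(0.7, 2.8)), window = 9L)
  f <- featureArray(fs)
  for (s in 1:2) {
    sums <- apply(f[, , (s - 1) * 7 + 1:7], c(1, 2), sum)
    expect_true(all(sums == 81L))  # reflective padding: borders included
  }
})

test_that("feature tables carry pixel coordinates and all features", {
  img <- matrix(runif(12 * 10), 12, 10)
  fs <- featureStack(bifStack(img, scales = 0.7), window = 3L)
  tab <- featuresAsTable(fs)
  expect_identical(nrow(tab), 120L)
  expect_identical(ncol(tab), 9L)  # row, col + 7 bins
  i <- which(tab$row == 5 & tab$col == 7)
  expect_equal(as.numeric(tab[i, -(1:2)]), as.numeric(featureArray(fs)[5, 7, ]))
})
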