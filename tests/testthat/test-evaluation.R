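test_that("the F-score formula and its edge cases hold", {
  expect_equal(fScore(new("ConfusionCounts", tp = 50, fp = 0, fn = 0,
                          tn = 0)), 1.0)
  expect_equal(fScore(new("ConfusionCounts", tp = 0, fp = 10, fn = 10,
                          tn = 0)), 0.0)
  expect_equal(fScore(new("ConfusionCounts", tp = 80, fp = 20, fn = 20,
                          tn = 0)), 0.8)
  expect_equal(fScore(80, fp = 20, fn = 20), 0.8)
  expect_error(fScore(new("ConfusionCounts", tp = 0, fp = 0, fn = 0,
                          tn = 5)), "undefined")
})

test_that("the F-score is FP/FN symmetric and monotone", {
  set.seed(2)
  for (i in 1:20) {
    tp <- sample(1:100, 1); fp <- sample(0:60, 1); fn <- sample(0:60, 1)
    expect_equal(fScore(tp, fp = fp, fn = fn), fScore(tp, fp = fn, fn = fp))
    expect_gte(fScore(tp, fp = fp, fn = fn),
               fScore(tp, fp = fp + 5, fn = fn))
    expect_gte(fScore(tp, fp = fp, fn = fn),
               fScore(tp, fp = fp, fn = fn + 5))
  }
})

test_that("confusion counts equal the exhaustive per-pixel tally", {
  set.seed(17)
  for (d in list(c(4, 4), c(16, 16), c(64, 64))) {
    pred <- matrix(rbinom(prod(d), 1, 0.5), d[1], d[2])
    ref <- matrix(rbinom(prod(d), 1, 0.5), d[1], d[2])
    cc <- confusionCounts(pred, ref)
    oracle <- bruteConfusion(pred, ref)
    expect_identical(c(tp = cc@tp, fp = cc@fp, fn = cc@fn, tn = cc@tn),
                     oracle + 0)
    expect_equal(cc@tp + cc@fp + cc@fn + cc@tn, prod(d))
  }
})

test_that("confusion handles identity, complement and bad shapes", {
  m <- matrix(rbinom(100, 1, 0.3), 10, 10)
  cc <- confusionCounts(m, m)
  expect_equal(cc@fp + cc@fn, 0)
  inv <- confusionCounts(1 - m, m)
  expect_equal(inv@tp + inv@tn, 0)
  expect_error(confusionCounts(m, matrix(0, 5, 5)), "shapes differ")
  expect_error(confusionCounts(m * 2, m), "binary")
})

test_that("confluency error summaries decompose as bias and precision", {
  zero <- matrix(0L, 10, 10)
  one <- zero; one[1, 1] <- 1L
  rep0 <- confluencyReport(list(one, one), list(one, one))
  expect_equal(rep0@bias, 0)
  expect_equal(rep0@rmse, 0)
  expect_equal(rep0@precisionStat, 0)
  expect_equal(rep0@meanF, 1)

  # deltas (+0.02, -0.02): bias 0, RMSE 0.02, precision 0.02
  ref <- matrix(0L, 10, 10); ref[1:5, ] <- 1L          # confluency 0.50
  up <- ref; up[6, 1:2] <- 1L                           # 0.52
  dn <- ref; dn[5, 1:2] <- 0L                           # 0.48
  rep2 <- confluencyReport(list(up, dn), list(ref, ref))
  expect_equal(rep2@bias, 0)
  expect_equal(rep2@rmse, 0.02)
  expect_equal(rep2@precisionStat, 0.02)
})

test_that("precision, bias and RMSE satisfy the exact identity", {
  set.seed(31)
  for (i in 1:5) {
    preds <- refs <- list()
    for (k in 1:6) {
      r <- matrix(rbinom(400, 1, 0.4), 20, 20)
      p <- r; flip <- sample(400, 25)
      p[flip] <- 1L - p[flip]
      if (sum(p == 1) + sum(r == 1) == 0) p[1] <- 1L
      preds[[k]] <- p; refs[[k]] <- r
    }
    rep <- confluencyReport(preds, refs)
    expect_equal(rep@precisionStat^2 + rep@bias^2, rep@rmse^2,
                 tolerance = 1e-12)
    expect_gte(rep@rmse, abs(rep@bias))
  }
})

test_that("the t-interval covers the true bias at its nominal rate", {
  set.seed(77)
  n_rep <- 200L
  covered <- logical(n_rep)
  trueBias <- 0  # symmetric pixel-count perturbation around the truth
  for (r in seq_len(n_rep)) {
    preds <- refs <- list()
    for (k in 1:8) {
      ref <- matrix(0L, 50, 50); ref[1:20, ] <- 1L
      shift <- round(rnorm(1, mean = 0, sd = 30))
      pred <- ref
      if (shift > 0) {
        zeros <- which(pred == 0L)
        pred[zeros[seq_len(min(shift, length(zeros)))]] <- 1L
      } else if (shift < 0) {
        ones <- which(pred == 1L)
        pred[ones[seq_len(min(-shift, length(ones)))]] <- 0L
      }
      preds[[k]] <- pred; refs[[k]] <- ref
    }
    rep <- suppressWarnings(confluencyReport(preds, refs))
    covered[r] <- rep@biasCI[1] <= trueBias && trueBias <= rep@biasCI[2]
  }
  expect_gt(mean(covered), 0.88)
  expect_lte(mean(covered), 1.0)
})

test_that("a single pair yields a report without a CI", {
  m <- matrix(0L, 8, 8); m[1:2, ] <- 1L
  expect_warning(rep1 <- confluencyReport(list(m), list(m)), "CI omitted")
  expect_true(all(is.na(rep1@biasCI)))
  expect_equal(rep1@meanF, 1)
})

test_that("agreement overlays colour-code the confusion classes", {
  ref <- matrix(0L, 4, 4); ref[1:2, ] <- 1L
  pred <- ref; pred[1, 1] <- 0L; pred[4, 4] <- 1L
  ov <- agreementOverlay(pred, ref)
  expect_equal(ov[2, 1, ], c(1, 1, 0))  # TP yellow
  expect_equal(ov[1, 1, ], c(1, 0, 0))  # FN red
  expect_equal(ov[4, 4, ], c(0, 1, 0))  # FP green
  expect_equal(ov[3, 1, ], c(0, 0, 0))  # TN black
})
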