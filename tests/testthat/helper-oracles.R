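## Independent brute-force oracles used to verify the fast paths.

# direct 2-D convolution with half-sample symmetric (reflective) padding;
# O(H W L^2) double loop, for small fixtures only
bruteConv2d <- function(img, kernel2d) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kernel2d); kw <- ncol(kernel2d)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  refl <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    j <- ifelse(j < 0L, j + 2L * n, j)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (cl in seq_len(W)) {
    acc <- 0
    for (dr in -ph:ph) for (dc in -pw:pw) {
      # convolution: kernel index at (dr,dc), image sample at (r-dr, c-dc)
      acc <- acc + kernel2d[dr + ph + 1L, dc + pw + 1L] *
        img[refl(r - dr, H), refl(cl - dc, W)]
    }
    out[r, cl] <- acc
  }
  out
}

# queue-based flood fill component labelling; supports 4- and 8-connectivity
bruteLabel <- function(mask, connectivity = 8L) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  if (connectivity == 8L) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (r in seq_len(H)) for (cl in seq_len(W)) {
    if (m[r, cl] == 1L && lab[r, cl] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(r, cl))
      lab[r, cl] <- nxt
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (k in seq_len(nrow(nb))) {
          rr <- p[1L] + nb[k, 1L]; cc <- p[2L] + nb[k, 2L]
          if (rr >= 1L && rr <= H && cc >= 1L && cc <= W &&
              m[rr, cc] == 1L && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# per-pixel confusion tally by explicit loop
bruteConfusion <- function(pred, ref) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && ref[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && ref[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && ref[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# outer product Gaussian-derivative kernel for the brute-force oracle
outerKernel <- function(sigma, orderX, orderY) {
  gk <- function(order) {
    r <- max(1L, ceiling(4 * sigma))
    x <- seq.int(-r, r)
    g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
    switch(as.character(order),
      "0" = g, "1" = -x / sigma^2 * g,
      "2" = {
        g2 <- (x^2 - sigma^2) / sigma^4 * g
        g2 - sum(g2) / length(g2)
      })
  }
  outer(gk(orderY), gk(orderX))  # rows = y, cols = x
}
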