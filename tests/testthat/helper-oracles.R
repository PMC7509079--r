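# Independent brute-force oracles used across the suite.

# 2-D binary dilation with a 3x3 square element, clipped at the border:
# direct double loop, no shared code with the package implementation.
brute_dilate2d <- function(m) {
  d <- dim(m)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (m[i, j] > 0) {
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) out[ii, jj] <- 1
      }
    }
  }
  out
}

# CSF ring by brute force: dilate twice, subtract the mask.
brute_ring2d <- function(m) {
  pmax(brute_dilate2d(brute_dilate2d(m)) - m, 0)
}

# OLS coefficients by normal equations.
brute_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Small, fast phantom used where full default resolution is not needed.
small_spec <- function(...) {
  args <- utils::modifyList(
    list(dim = c(40L, 40L, 48L), cord_radius = 4, ring_radius = 6.5,
         amplitude = 2, period = 40),
    list(...))
  do.call(phantom_spec, args)
}

# A compact asymmetric registration target: two fused Gaussian blobs give
# enough structure to pin down all nine transform parameters.
blob_volume <- function(n = 32L, shift = c(0, 0, 0)) {
  xs <- seq_len(n) - 1
  g <- expand.grid(x = xs, y = xs, z = xs)
  c1 <- c(13, 15, 14) + shift
  c2 <- c(19, 16, 18) + shift
  v <- exp(-((g$x - c1[1])^2 + (g$y - c1[2])^2 + (g$z - c1[3])^2) / 18) +
    0.7 * exp(-((g$x - c2[1])^2 + (g$y - c2[2])^2 + (g$z - c2[3])^2) / 10)
  image_volume(array(v, c(n, n, n)))
}

# A toy two-timepoint "halfway pair" of concentric noiseless tubes along z,
# built directly on a grid (no registration involved): cord radius r_b at
# baseline and r_f at follow-up inside a CSF bath.
toy_pair <- function(r_b = 4, r_f = 3.6, n = 32L, nz = 20L,
                     cord = 1, csf = 0.2) {
  cx <- (n - 1) / 2
  xs <- (0:(n - 1)) - cx
  d2 <- outer(xs^2, xs^2, "+")
  member <- function(r) {
    sl <- ifelse(sqrt(d2) < r, cord, csf)
    img <- array(rep(sl, nz), c(n, n, nz))
    msk <- array(rep((sqrt(d2) < r) * 1, nz), c(n, n, nz))
    list(image = image_volume(img), mask = cord_mask(msk))
  }
  list(baseline = member(r_b), followup = member(r_f))
}
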