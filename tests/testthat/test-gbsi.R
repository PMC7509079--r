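# Brute-force one-voxel 3-D morphology for small binary arrays.
brute_morph3d <- function(a, op = max) {
  d <- dim(a)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    vals <- c()
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      v <- if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
               kk >= 1 && kk <= d[3]) a[ii, jj, kk] else 0
      vals <- c(vals, v)
    }
    out[i, j, k] <- op(vals)
  }
  out
}

test_that("identical masks give a one-voxel shell around the boundary", {
  a <- array(0, c(9, 9, 9)); a[4:6, 4:6, 4:6] <- 1
  m <- cord_mask(a)
  reg <- boundary_region(m, m)
  oracle <- pmin(pmax(brute_morph3d(a, max) - brute_morph3d(a, min), 0), 1)
  expect_identical(reg$weights, oracle)
  expect_identical(reg$weights[5, 5, 5], 0)       # deep interior
  expect_identical(reg$weights[1, 1, 1], 0)       # far exterior
  expect_identical(reg$weights[3, 5, 5], 1)       # adjacent outside
  expect_identical(reg$weights[4, 5, 5], 1)       # boundary voxel
})

test_that("nested cylinders produce the dilated/eroded annulus", {
  pair <- toy_pair(r_b = 4.0, r_f = 3.6, n = 24L, nz = 8L)
  reg <- boundary_region(pair$baseline$mask, pair$followup$mask)
  b <- pair$baseline$mask$data
  f <- pair$followup$mask$data
  oracle <- pmin(pmax(pmax(brute_morph3d(b, max), brute_morph3d(f, max)) -
                        pmin(brute_morph3d(b, min), brute_morph3d(f, min)),
                      0), 1)
  expect_identical(reg$weights, oracle)
  # support covers every voxel where the masks disagree
  expect_true(all(reg$weights[b != f] > 0))
})

test_that("an empty follow-up mask is handled without error", {
  # with no follow-up object the erosion minimum vanishes everywhere, so
  # the whole (dilated) baseline support may have changed
  a <- array(0, c(9, 9, 9)); a[4:6, 4:6, 4:6] <- 1
  reg <- boundary_region(cord_mask(a), cord_mask(array(0, c(9, 9, 9))))
  oracle <- pmin(brute_morph3d(a, max), 1)
  expect_identical(reg$weights, oracle)
  bad <- cord_mask(array(0, c(8, 8, 8)))
  expect_error(boundary_region(cord_mask(a), bad), "grids")
})

test_that("normalization fixes the window and is intensity-scale invariant", {
  pair <- toy_pair(cord = 1, csf = 0.2)
  norm <- normalize_pair(pair)
  expect_equal(norm$window$low, 0.2, tolerance = 1e-6)
  expect_equal(norm$window$high, 1.0, tolerance = 1e-6)

  # multiplying one input by 10 changes nothing after normalization
  pair10 <- toy_pair(cord = 1, csf = 0.2)
  pair10$baseline$image$data <- pair10$baseline$image$data * 10
  norm10 <- normalize_pair(pair10)
  expect_equal(norm10$baseline$image$data, norm$baseline$image$data,
               tolerance = 1e-12)
  expect_equal(unlist(norm10$window), unlist(norm$window), tolerance = 1e-12)

  flat <- toy_pair(cord = 1, csf = 1)
  expect_error(normalize_pair(flat), "contrast")
})

test_that("the boundary-shift integral has its closed-form single-voxel value", {
  # identical images: exactly zero
  pair <- toy_pair(r_b = 4, r_f = 4)
  norm <- normalize_pair(pair)
  reg <- boundary_region(pair$baseline$mask, pair$followup$mask)
  expect_identical(bsi_volume(norm, reg, list(low = 0, high = 1)), 0)

  # one voxel flips cord -> CSF: dV = voxel volume, by the closed form
  pair2 <- toy_pair(r_b = 4, r_f = 4, cord = 1, csf = 0)
  pair2$followup$image$data[15, 15, 10] <- 0
  w <- array(0, dim(pair2$baseline$image$data)); w[15, 15, 10] <- 1
  region1 <- structure(list(weights = w, spacing = c(1, 1, 1),
                            voxel_volume = 1), class = "boundary_region")
  dv <- bsi_volume(pair2, region1, list(low = 0, high = 1))
  expect_equal(dv, 1, tolerance = 1e-12)

  # window validation
  expect_error(bsi_volume(pair2, region1, list(low = 1, high = 0)),
               "window")
})

test_that("nested-cylinder BSI recovers the true volume difference", {
  pair <- toy_pair(r_b = 4.0, r_f = 3.6, n = 32L, nz = 20L)
  true_dv <- sum(pair$baseline$mask$data - pair$followup$mask$data)
  reg <- boundary_region(pair$baseline$mask, pair$followup$mask)
  norm <- normalize_pair(pair)
  dv <- bsi_volume(norm, reg, norm$window)
  expect_equal(dv, true_dv, tolerance = 0.05)
})

test_that("percent-change conversion and annualization are exact", {
  res <- gbsi_percent_change(2, 100, 365.25)
  expect_identical(res$raw_pct, -2)
  expect_identical(res$annual_pct, -2)
  expect_identical(gbsi_percent_change(0, 50, 200)$annual_pct, 0)
  # 48-week interval: -0.92% raw annualizes by 365.25/336
  res48 <- atrophy_result(-0.92, 336)
  expect_equal(res48$annual_pct, -0.92 * 365.25 / 336, tolerance = 1e-12)
  expect_equal(res48$annual_pct, -1.00009, tolerance = 1e-4)
  expect_error(gbsi_percent_change(1, 0, 365.25), "positive")
  expect_error(atrophy_result(1, 0), "interval")
})

test_that("swapping timepoints negates the end-to-end GBSI", {
  pair <- make_phantom_pair(small_spec(atrophy = 0.02, sigma = 0))
  fwd <- measure_atrophy(pair$baseline, pair$followup, 365.25)
  rev <- measure_atrophy(pair$followup, pair$baseline, 365.25)
  # magnitudes differ slightly because the denominators differ; the
  # antisymmetry bound is on the raw percent changes
  expect_lt(abs(fwd$gbsi$raw_pct + rev$gbsi$raw_pct), 0.2)
  expect_lt(abs(fwd$csa$raw_pct + rev$csa$raw_pct), 0.2)
})

test_that("the end-to-end GBSI is invariant to global intensity scale", {
  pair <- make_phantom_pair(small_spec(atrophy = 0.02, sigma = 0))
  m1 <- measure_atrophy(pair$baseline, pair$followup, 365.25)
  scaled <- pair$baseline
  scaled$image$data <- scaled$image$data * 7.3
  m2 <- measure_atrophy(scaled, pair$followup, 365.25)
  expect_equal(m2$gbsi$annual_pct, m1$gbsi$annual_pct, tolerance = 1e-6)
})
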