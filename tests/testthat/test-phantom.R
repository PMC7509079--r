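test_that("phantom truth matches the requested atrophy fraction", {
  pair <- make_phantom_pair(small_spec(atrophy = 0.02, sigma = 0))
  expect_equal(pair$truth$percent_change, -2.0, tolerance = 0.02)
  ratio <- pair$truth$volume_followup / pair$truth$volume_baseline
  expect_equal(ratio, 0.98, tolerance = 4e-4)
  expect_gt(pair$truth$volume_baseline, 0)
  # truth record is self-consistent
  expect_equal(pair$truth$percent_change,
               100 * (pair$truth$volume_followup -
                        pair$truth$volume_baseline) /
                 pair$truth$volume_baseline)
})

test_that("noiseless mask voxel count recovers the volume-loss fraction", {
  # brute-force voxel count of the generated masks, binarized
  pair <- make_phantom_pair(small_spec(atrophy = 0.02, sigma = 0))
  vb <- sum(pair$baseline$mask$data >= 0.5)
  vf <- sum(pair$followup$mask$data >= 0.5)
  # one boundary-voxel layer bounds the discretization of a binary count
  spec <- pair$spec
  layer <- 2 * pi * spec$cord_radius * spec$dim[3] * spec$spacing[3]
  expect_lt(abs(vf / vb - 0.98), layer / (pi * spec$cord_radius^2 *
                                            spec$dim[3] * spec$spacing[3]))
  # the probabilistic (partial-volume) count is far tighter
  expect_equal(sum(pair$followup$mask$data) / sum(pair$baseline$mask$data),
               0.98, tolerance = 5e-4)
})

test_that("identical seeds and spec give bit-identical phantom pairs", {
  sp <- small_spec(atrophy = 0.03, sigma = 15, seed = 7L)
  a <- make_phantom_pair(sp)
  b <- make_phantom_pair(sp)
  expect_identical(a$baseline$image$data, b$baseline$image$data)
  expect_identical(a$followup$image$data, b$followup$image$data)
  expect_identical(a$truth, b$truth)
  # and a different seed gives different noise
  sp$seed <- 8L
  c <- make_phantom_pair(sp)
  expect_false(identical(a$baseline$image$data, c$baseline$image$data))
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(atrophy = -0.1), "atrophy")
  expect_error(phantom_spec(atrophy = 1), "atrophy")
  expect_error(phantom_spec(sigma = -1), "sigma")
  expect_error(phantom_spec(cord_radius = 8, ring_radius = 7), "exceed")
  expect_error(phantom_spec(spacing = c(1, 0, 1)), "positive")
  # cord leaving the grid is a geometry error
  expect_error(make_phantom_pair(phantom_spec(dim = c(16L, 16L, 48L))),
               "geometry")
})

test_that("Rician noise has the Rayleigh moments on zero signal", {
  img <- image_volume(array(0, c(40, 40, 40)))
  noisy <- add_rician_noise(img, sigma = 10, seed = 42L)
  # closed forms: mean = sigma * sqrt(pi/2), SD = sigma * sqrt(2 - pi/2)
  expect_equal(mean(noisy$data), 10 * sqrt(pi / 2), tolerance = 0.02)
  expect_equal(sd(noisy$data), 10 * sqrt(2 - pi / 2), tolerance = 0.02)
})

test_that("zero-sigma Rician noise is the identity and validation holds", {
  img <- image_volume(array(runif(27), c(3, 3, 3)))
  expect_identical(add_rician_noise(img, 0), img)
  expect_error(add_rician_noise(img, -1), "sigma")
  a <- add_rician_noise(img, 5, seed = 1L)
  b <- add_rician_noise(img, 5, seed = 1L)
  expect_identical(a$data, b$data)
})

test_that("phantom CSF ring noise matches the generating sigma", {
  # ring voxels between cord and ring radius carry the CSF level; their
  # post-noise SD must track sigma * sqrt(2 - pi/2) only for zero signal,
  # so probe the (near-)zero background instead
  sp <- small_spec(atrophy = 0, sigma = 12, seed = 3L,
                   intensities = c(cord = 500, csf = 100, background = 0))
  pair <- make_phantom_pair(sp)
  # brute-force the background region from the noiseless geometry
  clean <- make_phantom_pair(small_spec(atrophy = 0, sigma = 0,
                                        intensities = c(cord = 500,
                                                        csf = 100,
                                                        background = 0)))
  bg <- clean$baseline$image$data < 1e-9
  expect_gt(sum(bg), 1e4)
  expect_equal(sd(pair$baseline$image$data[bg]) / sqrt(2 - pi / 2), 12,
               tolerance = 0.05)
})

test_that("phantom pairs round-trip through NIfTI and JSON sidecars", {
  dir <- withr::local_tempdir()
  pair <- make_phantom_pair(small_spec(sigma = 5))
  write_phantom_pair(pair, dir)
  img <- read_volume(file.path(dir, "baseline.nii.gz"))
  msk <- read_volume(file.path(dir, "baseline_mask.nii.gz"), mask = TRUE)
  expect_equal(img$data, pair$baseline$image$data, tolerance = 1e-6)
  expect_equal(img$spacing, pair$baseline$image$spacing, tolerance = 1e-6)
  expect_s3_class(msk, "cord_mask")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$percent_change, pair$truth$percent_change)
})

test_that("segment_cord recovers the noiseless geometry", {
  sp <- small_spec(atrophy = 0, sigma = 0)
  pair <- make_phantom_pair(sp)
  lv <- sp$intensities
  seg <- segment_cord(pair$baseline$image, lv[["cord"]], lv[["csf"]])
  truth_bin <- (pair$baseline$mask$data >= 0.5) * 1
  expect_equal(seg$data, truth_bin, tolerance = 1e-12)
  expect_error(segment_cord(pair$baseline$image, 100, 500), "exceed")
})

test_that("simulated cohorts are reproducible with the stated moments", {
  co1 <- make_cohort(400, seed = 11L)
  co2 <- make_cohort(400, seed = 11L)
  expect_identical(co1, co2)
  expect_error(make_cohort(1), "n must be")

  # zero SD collapses onto the arm means exactly
  co0 <- make_cohort(50, rate_mean = c(placebo = -1.2, active = -0.4),
                     rate_sd = c(placebo = 0, active = 0), seed = 2L)
  expect_true(all(co0$rate[co0$arm == "placebo"] == -1.2))
  expect_true(all(co0$rate[co0$arm == "active"] == -0.4))

  # pooled mean within 3 SE of the common arm mean
  n <- 10000
  co <- make_cohort(n, rate_mean = c(placebo = -1.5, active = -1.5),
                    rate_sd = c(placebo = 3.1, active = 3.1), seed = 5L)
  se <- 3.1 / sqrt(n)
  expect_lt(abs(mean(co$rate) - (-1.5)), 3 * se)
  # EDSS stays on the half-point grid
  expect_true(all(abs(co$edss_baseline * 2 - round(co$edss_baseline * 2))
                  < 1e-9))
  expect_true(all(abs(co$edss_followup * 2 - round(co$edss_followup * 2))
                  < 1e-9))
})
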