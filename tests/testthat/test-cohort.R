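test_that("EDSS progression follows the two-branch rule exactly", {
  expect_true(edss_progression(4.0, 5.0))
  expect_false(edss_progression(5.5, 6.0))   # entry <= 5.5 needs a full point
  expect_true(edss_progression(6.0, 6.5))    # entry > 5.5: half point suffices
  # exhaustive boundary sweep over the half-point grid
  grid <- seq(0, 9.5, by = 0.5)
  for (b in grid) {
    for (d in c(0, 0.5, 1, 1.5)) {
      f <- min(b + d, 10)
      expected <- if (b <= 5.5) (f - b) >= 1 else (f - b) >= 0.5
      expect_identical(edss_progression(b, f), expected)
    }
  }
  expect_error(edss_progression(4.25, 5), "grid")
  expect_error(edss_progression(4, 11), "grid")
})

test_that("20%-worsening rule is boundary inclusive", {
  expect_true(score_progression(5.0, 6.0))     # exactly 20%
  expect_false(score_progression(5.0, 5.9))
  expect_true(score_progression(10, 12.1))
  expect_false(score_progression(10, 9))
  expect_error(score_progression(0, 5), "positive")
  # idempotent / deterministic
  expect_identical(score_progression(c(5, 5), c(6, 5.9)), c(TRUE, FALSE))
})

test_that("adjusted group difference matches normal equations on small data", {
  set.seed(1)
  n <- 40L
  dat <- data.frame(
    arm = rep(c("placebo", "active"), each = n / 2),
    age = rnorm(n, 45, 5), sex = sample(c("male", "female"), n, TRUE),
    height = rnorm(n, 170, 8),
    country = sample(c("c1", "c2", "c3"), n, TRUE),
    baseline_csa = rnorm(n, 70, 6))
  dat$rate <- -1 + 0.5 * (dat$arm == "active") + 0.02 * dat$age +
    rnorm(n, 0, 0.5)
  res <- adjusted_group_diff(dat)
  X <- stats::model.matrix(~ stats::relevel(factor(arm), "placebo") + age +
                             sex + height + country + baseline_csa, dat)
  beta <- brute_ols(X, dat$rate)
  expect_equal(res$coefficient, beta[2], tolerance = 1e-10)
  expect_lt(res$ci_lower, res$coefficient)
  expect_gt(res$ci_upper, res$coefficient)
  expect_identical(res$n, n)
})

test_that("a noiseless linear outcome is recovered exactly", {
  set.seed(3)
  n <- 60
  dat <- data.frame(
    arm = rep(c("placebo", "active"), each = n / 2),
    age = rnorm(n, 45, 5), sex = sample(c("male", "female"), n, TRUE),
    height = rnorm(n, 170, 8), country = sample(c("c1", "c2"), n, TRUE),
    baseline_csa = rnorm(n, 70, 6))
  dat$rate <- 2 * (dat$arm == "active") + 0.1 * dat$age - 0.05 * dat$height
  res <- suppressWarnings(adjusted_group_diff(dat))  # perfect-fit warning
  expect_equal(res$coefficient, 2, tolerance = 1e-8)
  expect_lt(res$p_value, 1e-10)
})

test_that("rank-deficient designs error with the collinear column named", {
  set.seed(4)
  n <- 30
  dat <- data.frame(
    arm = rep(c("placebo", "active"), each = n / 2),
    age = rnorm(n, 45, 5), sex = "male", height = rnorm(n, 170, 8),
    country = "c1", baseline_csa = rnorm(n, 70, 6))
  dat$dup <- dat$age  # exact copy
  dat$rate <- rnorm(n)
  expect_error(
    adjusted_group_diff(dat, covariates = c("age", "dup", "height",
                                            "baseline_csa")),
    "collinear.*dup")
  expect_error(adjusted_group_diff(dat[, -1]), "missing columns")
})

test_that("arm comparison keeps nominal type-I error under the null", {
  set.seed(6)
  reps <- 400
  rejections <- 0
  for (i in seq_len(reps)) {
    co <- make_cohort(200, rate_mean = c(placebo = -1, active = -1),
                      rate_sd = c(placebo = 3, active = 3), seed = 1000L + i)
    res <- adjusted_group_diff(co)
    if (res$p_value < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / reps
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("arm comparison recovers a true adjusted difference", {
  co <- make_cohort(5000, rate_mean = c(placebo = -1.0, active = -1.8),
                    rate_sd = c(placebo = 3.1, active = 3.1), seed = 77L)
  res <- adjusted_group_diff(co)
  se <- (res$ci_upper - res$ci_lower) / (2 * qnorm(0.975))
  expect_lt(abs(res$coefficient - (-0.8)), 3 * se)
  expect_lt(res$p_value, 0.05)
})

test_that("backward selection keeps strong candidates and drops noise", {
  set.seed(8)
  n <- 400
  co <- make_cohort(n, seed = 12L)
  co$flag_true <- runif(n) < 0.3
  co$flag_noise1 <- runif(n) < 0.3
  co$flag_noise2 <- runif(n) < 0.3
  co$rate <- co$rate - 2.5 * co$flag_true
  sel <- backward_select(co, "rate",
                         c("flag_true", "flag_noise1", "flag_noise2"))
  expect_true("flag_true" %in% sel$retained)
  expect_equal(sel$results$flag_true$coefficient, -2.5, tolerance = 0.6)
  # termination bound: every candidate is visited at most once
  expect_lte(length(sel$dropped) + length(sel$retained), 3L)
})

test_that("all-noise candidates are retained at roughly the stay threshold", {
  set.seed(13)
  reps <- 150
  n <- 250
  retained <- 0
  total <- 0
  for (i in seq_len(reps)) {
    co <- make_cohort(n, seed = 5000L + i)
    for (k in 1:3) co[[paste0("flag", k)]] <- runif(n) < 0.3
    sel <- backward_select(co, "rate", paste0("flag", 1:3))
    retained <- retained + length(sel$retained)
    total <- total + 3
  }
  rate <- retained / total
  # per-candidate retention should sit near the p = 0.20 stay threshold
  expect_gt(rate, 0.12)
  expect_lt(rate, 0.30)
})
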