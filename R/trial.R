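#' Sample size per arm for a two-arm trial on an atrophy rate
#'
#' Standard two-sample normal approximation for a 1:1 randomized
#' placebo-controlled trial with a continuous outcome:
#' `n = ceiling(2 * (z_{1-alpha/2} + z_{power})^2 * sd^2 / delta^2)`,
#' where the detectable difference is `delta = effect * |mean|`, i.e. the
#' treatment is assumed to remove a fraction `effect` of the mean atrophy
#' rate. Alpha is two-sided; rounding is ceiling (the minimal integer n
#' meeting the formula).
#'
#' @param mean Mean annualized atrophy rate (%/year); the sign is ignored.
#' @param sd Standard deviation of the rate (> 0).
#' @param effect Treatment effect fraction in (0, 1].
#' @param alpha Two-sided type-I error rate.
#' @param power Target power.
#' @return Integer sample size per arm.
#' @export
sample_size <- function(mean, sd, effect, alpha = 0.05, power = 0.80) {
  if (!is.finite(mean) || mean == 0)
    stop_input("sample_size: mean rate is 0, effect size undefined")
  if (!is.finite(sd) || sd <= 0) stop_input("sample_size: sd must be > 0")
  if (effect <= 0 || effect > 1)
    stop_input("sample_size: effect must be in (0, 1]")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop_input("sample_size: alpha and power must be in (0, 1)")
  delta <- effect * abs(mean)
  zsum <- qnorm(1 - alpha / 2) + qnorm(power)
  as.integer(ceiling(2 * zsum^2 * sd^2 / delta^2))
}

#' Sample sizes over a grid of simulated treatment effects
#'
#' @inheritParams sample_size
#' @param effects Treatment effect fractions (default 30/60/90%).
#' @return A data.frame of class `trial_design_result` with one row per
#'   effect (`effect`, `n_per_arm`), plus attributes `mean` and `sd`.
#' @export
effect_grid <- function(mean, sd, effects = c(0.30, 0.60, 0.90),
                        alpha = 0.05, power = 0.80) {
  n <- vapply(effects, function(e) sample_size(mean, sd, e, alpha, power),
              integer(1))
  out <- data.frame(effect = effects, n_per_arm = n)
  attr(out, "mean") <- mean
  attr(out, "sd") <- sd
  class(out) <- c("trial_design_result", "data.frame")
  out
}

#' Coefficient of variation of atrophy rates
#'
#' Sample SD divided by the mean, signed: negative mean rates give negative
#' coefficients.
#'
#' @param values Numeric vector (>= 2 values, nonzero mean).
#' @return The coefficient of variation.
#' @export
coeff_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop_input("coeff_variation: need >= 2 values")
  m <- mean(values)
  if (m == 0) stop_input("coeff_variation: mean is zero")
  sd(values) / m
}

#' Median absolute deviation of atrophy rates
#'
#' Raw (unscaled) median of absolute deviations from the median -- no
#' normal-consistency factor.
#'
#' @param values Numeric vector (>= 1 value).
#' @return The median absolute deviation, in the units of `values`.
#' @export
median_abs_dev <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop_input("median_abs_dev: empty input")
  median(abs(values - median(values)))
}

#' Monte-Carlo verification of the sample-size formula
#'
#' Simulates `reps` two-arm trials of size `n` per arm: placebo rates from
#' `N(|mean|, sd)`, treated rates from `N(|mean| * (1 - effect), sd)`, and a
#' two-sample z-test (pooled sample SD) at two-sided level `alpha`. Returns
#' the rejection fraction -- the empirical power (or, at `effect = 0`, the
#' empirical type-I error).
#'
#' @inheritParams sample_size
#' @param effect Treatment effect fraction in \[0, 1\] (0 checks type-I
#'   calibration).
#' @param n Sample size per arm.
#' @param reps Number of simulated trials (>= 100).
#' @param seed Optional RNG seed.
#' @return Empirical rejection fraction.
#' @export
verify_power <- function(mean, sd, effect, n, alpha = 0.05,
                         reps = 10000, seed = NULL) {
  if (reps < 100) stop_input("verify_power: reps must be >= 100")
  if (effect < 0 || effect > 1)
    stop_input("verify_power: effect must be in [0, 1]")
  n <- as.integer(n)
  mu0 <- abs(mean)
  mu1 <- mu0 * (1 - effect)
  zcrit <- qnorm(1 - alpha / 2)
  with_seed(seed, {
    rejected <- 0L
    chunk <- max(1L, min(reps, as.integer(2e6 / n)))
    done <- 0L
    while (done < reps) {
      m <- min(chunk, reps - done)
      a <- matrix(rnorm(n * m, mu0, sd), n, m)
      b <- matrix(rnorm(n * m, mu1, sd), n, m)
      da <- colMeans(a); db <- colMeans(b)
      va <- (colSums(a^2) - n * da^2) / (n - 1)
      vb <- (colSums(b^2) - n * db^2) / (n - 1)
      z <- (da - db) / sqrt((va + vb) / n)
      rejected <- rejected + sum(abs(z) > zcrit)
      done <- done + m
    }
    rejected / reps
  })
}
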