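#' Simulate a two-arm cohort table
#'
#' Draws a synthetic cohort for the trial-design and cohort-statistics
#' tools: annualized atrophy rates per arm from normal distributions,
#' demographic covariates from ranges typical of a progressive MS trial
#' population (age 25-55 y, ~54% male, height ~172 +- 10 cm, ten country
#' labels), baseline EDSS on the 0.5-step 3.0-6.5 grid, and
#' baseline/follow-up clinical scores (T25FW, 9HPT, SDMT, MSWS) whose
#' follow-up values meet the 20%-worsening progression rule with the stated
#' per-outcome probabilities.
#'
#' @param n Number of subjects (>= 2), split 1:1 between placebo and active.
#' @param rate_mean Named length-2 numeric: mean annualized atrophy rate
#'   (%/year) for `placebo` and `active`.
#' @param rate_sd Named length-2 numeric: SD of the rate per arm (>= 0).
#' @param prog_prob Named probabilities of progression for `EDSS`, `T25FW`,
#'   `9HPT`, `SDMT`, `MSWS`.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A data.frame with one row per subject.
#' @export
make_cohort <- function(n,
                        rate_mean = c(placebo = -1.5, active = -1.5),
                        rate_sd = c(placebo = 3.1, active = 3.1),
                        prog_prob = c(EDSS = 0.24, T25FW = 0.26,
                                      `9HPT` = 0.09, SDMT = 0.25,
                                      MSWS = 0.15),
                        seed = 1L) {
  if (!is.numeric(n) || n < 2) stop_input("make_cohort: n must be >= 2")
  n <- as.integer(n)
  if (any(rate_sd < 0)) stop_input("make_cohort: rate SDs must be >= 0")
  stopifnot(all(c("placebo", "active") %in% names(rate_mean)),
            all(c("placebo", "active") %in% names(rate_sd)))

  with_seed(seed, {
    arm <- sample(rep(c("placebo", "active"), length.out = n))
    age <- clamp(rnorm(n, 46.5, 6.8), 25, 55)
    sex <- ifelse(runif(n) < 0.536, "male", "female")
    height <- rnorm(n, 172, 9.8)
    country <- sample(sprintf("country%02d", 1:10), n, replace = TRUE)
    baseline_csa <- rnorm(n, 72, 7)

    rate <- rnorm(n, rate_mean[arm], rate_sd[arm])

    edss_grid <- seq(3, 6.5, by = 0.5)
    edss_b <- sample(edss_grid, n, replace = TRUE)
    edss_prog <- runif(n) < prog_prob[["EDSS"]]
    edss_f <- ifelse(edss_prog,
                     pmin(edss_b + ifelse(edss_b <= 5.5, 1, 0.5), 10),
                     edss_b)

    prog_score <- function(baseline, p) {
      prog <- runif(n) < p
      fac <- ifelse(prog, runif(n, 1.20, 1.50), runif(n, 0.85, 1.15))
      baseline * fac
    }
    t25fw_b <- exp(rnorm(n, log(8), 0.35))
    hpt_b <- exp(rnorm(n, log(25), 0.25))
    sdmt_b <- pmax(round(rnorm(n, 45, 10)), 5)
    msws_b <- clamp(rnorm(n, 55, 18), 12, 96)

    data.frame(
      subject = sprintf("S%04d", seq_len(n)),
      arm = arm, age = age, sex = sex, height = height, country = country,
      baseline_csa = baseline_csa, rate = rate,
      edss_baseline = edss_b, edss_followup = edss_f,
      t25fw_baseline = t25fw_b,
      t25fw_followup = prog_score(t25fw_b, prog_prob[["T25FW"]]),
      hpt9_baseline = hpt_b,
      hpt9_followup = prog_score(hpt_b, prog_prob[["9HPT"]]),
      sdmt_baseline = sdmt_b,
      sdmt_followup = prog_score(sdmt_b, prog_prob[["SDMT"]]),
      msws_baseline = msws_b,
      msws_followup = prog_score(msws_b, prog_prob[["MSWS"]]),
      stringsAsFactors = FALSE)
  })
}

#' Write / read a cohort table
#'
#' Plain CSV with the documented [make_cohort()] header.
#'
#' @param cohort A cohort data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
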