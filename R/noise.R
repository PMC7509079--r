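#' Extract the CSF ring surrounding the cord
#'
#' Per axial slice, the mask (binarized at 0.5) is dilated twice with a 3x3
#' square structuring element and the original mask is subtracted, leaving a
#' two-pixel in-plane ring around the cord. Slices with no cord contribute
#' nothing; at the image border the ring is clipped, not padded.
#'
#' @param mask A [cord_mask()].
#' @return A binary [cord_mask()] marking ring voxels.
#' @export
csf_ring <- function(mask) {
  stopifnot(inherits(mask, "cord_mask"))
  bin <- mask$data >= 0.5
  if (!any(bin)) stop_input("csf_ring: mask is empty")
  ring <- array(0, dim(bin))
  for (k in seq_len(dim(bin)[3])) {
    sl <- bin[, , k] * 1
    if (!any(sl > 0)) next
    dil <- dilate2d_1(dilate2d_1(sl))
    ring[, , k] <- pmax(dil - sl, 0)
  }
  if (!any(ring > 0))
    stop_input("csf_ring: ring is empty (mask fills every nonzero slice)")
  cord_mask(ring, mask$spacing)
}

#' One-sided outlier rejection for ring intensities
#'
#' Single pass: values strictly greater than `mean + 2 * SD` (population SD)
#' are discarded; values below the mean are never removed. This is meant to
#' drop spurious bright structures (nerve roots) from the CSF ring before
#' the noise SD is computed.
#'
#' @param values Numeric vector, length >= 2.
#' @return The retained values.
#' @export
reject_outliers <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop_input("reject_outliers: need at least 2 values")
  thr <- mean(values) + 2 * population_sd(values)
  values[values <= thr]
}

#' Noise-floor estimate from CSF-ring intensities
#'
#' Applies [reject_outliers()], takes the (population) standard deviation of
#' the retained magnitude intensities as `sigma_eta`, and corrects for the
#' Rayleigh statistics of magnitude-reconstructed signal-free regions:
#' `sigma = sigma_eta / sqrt(2 - pi/2)`, the Gaussian channel SD.
#'
#' Note that on ideal pure-noise (Rayleigh) rings the one-sided trim removes
#' about 3.7% of the legitimate upper tail, attenuating the estimate by a
#' factor of about 0.88; set `reject = FALSE` for an unbiased estimate on
#' contamination-free data.
#'
#' @param values Ring intensity values (>= 2 after rejection).
#' @param level Optional level label carried into the estimate.
#' @param reject Apply the outlier-rejection pass (default `TRUE`, the
#'   standard procedure).
#' @return A list of class `noise_estimate`: `n_before`, `n_after`,
#'   `sigma_eta`, `sigma`, `level`.
#' @export
noise_sigma <- function(values, level = NA_character_, reject = TRUE) {
  values <- as.numeric(values)
  n_before <- length(values)
  kept <- if (reject) reject_outliers(values) else values
  if (length(kept) < 2L)
    stop_input("noise_sigma: fewer than 2 values after rejection")
  sigma_eta <- population_sd(kept)
  structure(list(n_before = n_before, n_after = length(kept),
                 sigma_eta = sigma_eta,
                 sigma = sigma_eta / sqrt(2 - pi / 2),
                 level = level),
            class = "noise_estimate")
}

#' Noise-floor estimate for an image/mask pair
#'
#' Convenience wrapper: extracts the CSF ring from the mask and estimates
#' the noise floor from the image intensities inside it.
#'
#' @param img An [image_volume()].
#' @param mask The matching [cord_mask()].
#' @inheritParams noise_sigma
#' @return A `noise_estimate`.
#' @export
noise_floor <- function(img, mask, level = NA_character_, reject = TRUE) {
  if (!same_grid(img, mask))
    stop_input("noise_floor: image and mask grids differ")
  ring <- csf_ring(mask)
  noise_sigma(img$data[ring$data > 0.5], level = level, reject = reject)
}

#' Classify scans against the per-level median noise floor
#'
#' A scan is "above the median quality" when its sigma does not exceed the
#' median sigma of its level (lower noise is better); the median is computed
#' independently per level label.
#'
#' @param sigma Numeric vector of noise-floor estimates.
#' @param level Level label per estimate (recycled if length 1).
#' @return Logical vector: `TRUE` when `sigma <= median(level sigmas)`.
#' @export
classify_by_median <- function(sigma, level = "all") {
  sigma <- as.numeric(sigma)
  if (length(sigma) < 1L) stop_input("classify_by_median: no estimates")
  level <- rep_len(as.character(level), length(sigma))
  med <- tapply(sigma, level, median)
  as.vector(sigma <= unname(med[level]))
}

#' Implausibility decision for a CSA/GBSI rate pair
#'
#' A measurement at a given cord level is excluded only when *both* the CSA
#' and the GBSI annualized rates exceed the plausibility cut-off in absolute
#' value (default 5 %/year, two standard deviations of the healthy-control
#' atrophy rate). The rule is two-sided and conjunctive; if either value is
#' missing the decision is deferred and flagged incomplete.
#'
#' @param csa_pct,gbsi_pct Annualized percent-change values (vectors).
#' @param subject,level Optional identifiers carried into the output.
#' @param threshold Cut-off in percent (default 5).
#' @return A data.frame of QC decisions with columns `subject`, `level`,
#'   `csa_pct`, `gbsi_pct`, `excluded`, `incomplete`, `reason`.
#' @export
implausible_pair <- function(csa_pct, gbsi_pct, subject = NA_character_,
                             level = NA_character_, threshold = 5) {
  n <- max(length(csa_pct), length(gbsi_pct))
  csa_pct <- rep_len(as.numeric(csa_pct), n)
  gbsi_pct <- rep_len(as.numeric(gbsi_pct), n)
  subject <- rep_len(as.character(subject), n)
  level <- rep_len(as.character(level), n)
  incomplete <- is.na(csa_pct) | is.na(gbsi_pct)
  excluded <- !incomplete & abs(csa_pct) > threshold & abs(gbsi_pct) > threshold
  reason <- ifelse(incomplete, "missing value: decision deferred",
            ifelse(excluded,
                   sprintf("implausible: |CSA| and |GBSI| both > %g%%",
                           threshold),
                   "retained"))
  data.frame(subject = subject, level = level,
             csa_pct = csa_pct, gbsi_pct = gbsi_pct,
             excluded = excluded, incomplete = incomplete,
             reason = reason, stringsAsFactors = FALSE)
}

#' Apply the implausibility filter to a cohort of rate pairs
#'
#' @param rates A data.frame with columns `csa_pct` and `gbsi_pct` (and
#'   optionally `subject`, `level`).
#' @param threshold Cut-off in percent.
#' @return List with `decisions` (per-row QC decisions), `retained` (the
#'   filtered data.frame) and `summary` (counts per disposition).
#' @export
qc_cohort <- function(rates, threshold = 5) {
  stopifnot(is.data.frame(rates),
            all(c("csa_pct", "gbsi_pct") %in% names(rates)))
  dec <- implausible_pair(
    rates$csa_pct, rates$gbsi_pct,
    subject = if ("subject" %in% names(rates)) rates$subject else NA,
    level = if ("level" %in% names(rates)) rates$level else NA,
    threshold = threshold)
  list(decisions = dec,
       retained = rates[!dec$excluded, , drop = FALSE],
       summary = c(total = nrow(dec),
                   excluded = sum(dec$excluded),
                   incomplete = sum(dec$incomplete),
                   retained = sum(!dec$excluded)))
}
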