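#' Specification of a longitudinal cord phantom pair
#'
#' Describes a curved tubular "spinal cord" of known radius inside a CSF
#' ring, imaged at two timepoints with a known atrophy fraction between them
#' and magnitude (Rician) noise of known Gaussian-channel sigma. The phantom
#' is the ground-truth oracle for the whole measurement stack: the cord
#' shrinks radially by `sqrt(1 - atrophy)` at follow-up so the true percent
#' volume change is exactly `-100 * atrophy`, the vacated shell is filled by
#' CSF, and partial volume at the cord and ring boundaries is modelled by
#' 3x-per-axis supersampling of boundary voxels.
#'
#' @param dim Grid shape in voxels (length 3).
#' @param spacing Voxel spacing in mm (length 3, all > 0).
#' @param cord_radius Cord tube radius in mm.
#' @param ring_radius Outer radius of the surrounding CSF ring in mm
#'   (must exceed `cord_radius`).
#' @param amplitude,period Amplitude and period (mm) of the sinusoidal bend
#'   of the cord centerline in the x-z plane; `amplitude = 0` gives a
#'   straight cylinder.
#' @param intensities Named numeric vector with elements `cord`, `csf` and
#'   `background` (arbitrary units).
#' @param atrophy Fraction `f` of cord volume lost at follow-up, `0 <= f < 1`.
#' @param sigma Gaussian channel noise SD (same units as `intensities`);
#'   `0` gives noiseless images.
#' @param interval Days between the two timepoints; used for annualization.
#'   The default of one year makes annualized rates equal raw percent change.
#' @param seed Integer seed controlling the noise draws.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(48L, 48L, 64L),
                         spacing = c(1, 1, 1),
                         cord_radius = 4.5,
                         ring_radius = 7.5,
                         amplitude = 2.5,
                         period = 50,
                         intensities = c(cord = 500, csf = 100, background = 20),
                         atrophy = 0.02,
                         sigma = 0,
                         interval = 365.25,
                         seed = 1L) {
  dim <- as.integer(dim)
  spacing <- as.numeric(spacing)
  if (length(dim) != 3L || any(dim < 8L))
    stop_input("phantom_spec: dim must be 3 integers >= 8")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_input("phantom_spec: spacing must be positive on all axes")
  if (!is.finite(cord_radius) || cord_radius <= 0)
    stop_input("phantom_spec: cord_radius must be positive")
  if (ring_radius <= cord_radius)
    stop_input("phantom_spec: ring_radius (%.3g) must exceed cord_radius (%.3g)",
               ring_radius, cord_radius)
  if (!all(c("cord", "csf", "background") %in% names(intensities)))
    stop_input("phantom_spec: intensities needs cord, csf and background")
  if (atrophy < 0 || atrophy >= 1)
    stop_input("phantom_spec: atrophy fraction must satisfy 0 <= f < 1")
  if (sigma < 0) stop_input("phantom_spec: sigma must be >= 0")
  if (interval <= 0) stop_input("phantom_spec: interval must be positive days")
  structure(list(dim = dim, spacing = spacing, cord_radius = cord_radius,
                 ring_radius = ring_radius, amplitude = amplitude,
                 period = period, intensities = intensities,
                 atrophy = atrophy, sigma = sigma, interval = interval,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Centerline position (mm) at axial coordinate z (mm): a sinusoid in the
# x-z plane through the in-plane grid centre.
phantom_centerline_fun <- function(spec) {
  xc <- (spec$dim[1] - 1) / 2 * spec$spacing[1]
  yc <- (spec$dim[2] - 1) / 2 * spec$spacing[2]
  a <- spec$amplitude
  p <- spec$period
  function(z) cbind(xc + a * sin(2 * pi * z / p), rep(yc, length(z)), z)
}

# Minimum distance from points to the centerline curve, computed slicewise:
# for points near axial coordinate z only curve samples within +-window
# matter (the tube radius bounds how far along the curve the nearest point
# can be).
min_dist_to_curve <- function(px, py, pz, curve, window) {
  n <- length(px)
  out <- numeric(n)
  zs <- sort(unique(round(pz, 9)))
  for (z0 in zs) {
    sel <- which(abs(pz - z0) < 1e-9)
    csel <- which(abs(curve[, 3] - z0) <= window)
    dmin <- rep(Inf, length(sel))
    x <- px[sel]; y <- py[sel]
    for (j in csel) {
      d2 <- (x - curve[j, 1])^2 + (y - curve[j, 2])^2 + (z0 - curve[j, 3])^2
      dmin <- pmin(dmin, d2)
    }
    out[sel] <- sqrt(dmin)
  }
  out
}

# Partial-volume occupancy of a tube of radius r around the phantom
# centerline: exact 0/1 away from the boundary, 3x3x3 supersampled fraction
# for voxels whose centre lies within half a voxel diagonal of the surface.
tube_fractions <- function(spec, radii) {
  d <- spec$dim; sp <- spec$spacing
  cl <- phantom_centerline_fun(spec)
  window <- spec$ring_radius + 3 * max(sp)
  zmax <- (d[3] - 1) * sp[3]
  curve <- cl(seq(-window, zmax + window, by = min(sp) / 4))

  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zsl <- (seq_len(d[3]) - 1) * sp[3]
  vx <- rep(xs, times = d[2] * d[3])
  vy <- rep(rep(ys, each = d[1]), times = d[3])
  vz <- rep(zsl, each = d[1] * d[2])
  dist <- min_dist_to_curve(vx, vy, vz, curve, window)

  hd <- sqrt(sum((sp / 2)^2))  # half voxel diagonal
  band <- rep(FALSE, length(dist))
  for (r in radii) band <- band | (abs(dist - r) < hd)

  sub <- NULL
  if (any(band)) {
    off <- c(-1, 0, 1) / 3
    offs <- as.matrix(expand.grid(off * sp[1], off * sp[2], off * sp[3]))
    bi <- which(band)
    nb <- length(bi)
    spx <- rep(vx[bi], each = 27L) + rep(offs[, 1], times = nb)
    spy <- rep(vy[bi], each = 27L) + rep(offs[, 2], times = nb)
    spz <- rep(vz[bi], each = 27L) + rep(offs[, 3], times = nb)
    sub <- min_dist_to_curve(spx, spy, spz, curve, window)
  }

  # Each boundary subvoxel contributes a planar-cut occupancy ramp of its
  # own width rather than a hard 0/1 count: the surface shell between two
  # nearby radii is much thinner than the subvoxel lattice, and hard counts
  # alias badly against it.
  sub_h <- mean(sp) / 3
  lapply(radii, function(r) {
    frac <- as.numeric(dist < r)
    if (any(band)) {
      occ <- matrix(clamp(0.5 + (r - sub) / sub_h, 0, 1), nrow = 27L)
      frac[which(band)] <- colMeans(occ)
    }
    array(frac, d)
  })
}

#' Add Rician (magnitude-reconstructed) noise to a volume
#'
#' Each voxel becomes the magnitude of the true signal plus complex Gaussian
#' noise with per-channel standard deviation `sigma`:
#' `sqrt((I + n1)^2 + n2^2)`. In signal-free regions the output is Rayleigh
#' distributed with mean `sigma * sqrt(pi/2)` and SD `sigma * sqrt(2 - pi/2)`.
#'
#' @param img An [image_volume()].
#' @param sigma Gaussian channel SD; `0` returns the input unchanged.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An [image_volume()] with noisy intensities.
#' @export
add_rician_noise <- function(img, sigma, seed = NULL) {
  stopifnot(inherits(img, "image_volume"))
  if (!is.finite(sigma) || sigma < 0)
    stop_input("add_rician_noise: sigma must be >= 0")
  if (sigma == 0) return(img)
  with_seed(seed, {
    n <- length(img$data)
    re <- img$data + array(rnorm(n, 0, sigma), dim(img$data))
    im <- array(rnorm(n, 0, sigma), dim(img$data))
    image_volume(sqrt(re^2 + im^2), img$spacing)
  })
}

#' Generate a baseline/follow-up phantom pair with known ground truth
#'
#' Builds both timepoints on the shared grid: the follow-up cord radius is
#' `cord_radius * sqrt(1 - f)` so that follow-up cord volume equals
#' `baseline * (1 - f)` for the fixed centerline, and the CSF ring fills the
#' vacated shell. Noise is drawn independently per timepoint from the spec
#' seed. The truth record holds the noiseless mask volumes, the implied
#' percent volume change, the generating noise sigma and the centerline
#' polyline.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_pair` with elements `baseline` and
#'   `followup` (each `list(image, mask)`), `truth`, and `spec`.
#' @export
make_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  fov_x <- (spec$dim[1] - 1) * sp[1]
  reach <- spec$amplitude + spec$ring_radius + max(sp)
  if (reach > fov_x / 2)
    stop_input(paste0("make_phantom_pair: geometry error - cord/ring ",
                      "(reach %.1f mm) leaves the grid (half-FOV %.1f mm)"),
               reach, fov_x / 2)

  r_b <- spec$cord_radius
  r_f <- spec$cord_radius * sqrt(1 - spec$atrophy)
  fr <- tube_fractions(spec, c(r_b, r_f, spec$ring_radius))
  frac_b <- fr[[1]]; frac_f <- fr[[2]]; frac_ring <- fr[[3]]

  lv <- spec$intensities
  img_b <- lv[["background"]] + (lv[["csf"]] - lv[["background"]]) * frac_ring +
    (lv[["cord"]] - lv[["csf"]]) * frac_b
  img_f <- lv[["background"]] + (lv[["csf"]] - lv[["background"]]) * frac_ring +
    (lv[["cord"]] - lv[["csf"]]) * frac_f

  baseline <- image_volume(img_b, sp)
  followup <- image_volume(img_f, sp)
  if (spec$sigma > 0) {
    pair_noise <- with_seed(spec$seed, list(
      b = add_rician_noise(baseline, spec$sigma),
      f = add_rician_noise(followup, spec$sigma)))
    baseline <- pair_noise$b
    followup <- pair_noise$f
  }

  voxvol <- prod(sp)
  vol_b <- sum(frac_b) * voxvol
  vol_f <- sum(frac_f) * voxvol
  cl <- phantom_centerline_fun(spec)((seq_len(spec$dim[3]) - 1) * sp[3])

  truth <- list(
    volume_baseline = vol_b,
    volume_followup = vol_f,
    percent_change = 100 * (vol_f - vol_b) / vol_b,
    atrophy_fraction = spec$atrophy,
    sigma = spec$sigma,
    interval = spec$interval,
    centerline = cl)

  structure(list(
    baseline = list(image = baseline, mask = cord_mask(frac_b, sp)),
    followup = list(image = followup, mask = cord_mask(frac_f, sp)),
    truth = truth, spec = spec), class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf(
    "<phantom_pair> f = %.3g, sigma = %.3g, true change %.3f%% over %.4g d\n",
    x$spec$atrophy, x$spec$sigma, x$truth$percent_change, x$truth$interval))
  invisible(x)
}

#' Threshold-based probabilistic cord segmentation
#'
#' Emulates the measurement step that produces cord masks from (noisy)
#' images in a real pipeline: intensity is mapped linearly onto a cord
#' probability between the CSF and cord reference levels,
#' `p = clamp((I - csf) / (cord - csf), 0, 1)`, optionally after a 3x3x3 box
#' smoothing, and by default binarized at 0.5 -- automated segmenters emit
#' (near-)binary masks, and it is exactly this boundary quantization,
#' driven by image noise, that gives segmentation-based area measures their
#' scan-to-scan variability.
#'
#' @param img An [image_volume()].
#' @param cord,csf Reference intensities of cord tissue and CSF.
#' @param smooth If `TRUE`, box-smooth the image before thresholding.
#' @param binary Binarize the probability map at 0.5 (default), as a CNN
#'   segmenter effectively does; `FALSE` keeps the linear partial-volume
#'   probabilities.
#' @return A [cord_mask()].
#' @export
segment_cord <- function(img, cord, csf, smooth = FALSE, binary = TRUE) {
  stopifnot(inherits(img, "image_volume"))
  if (cord <= csf) stop_input("segment_cord: cord intensity must exceed csf")
  x <- img$data
  if (smooth) x <- boxmean3d_1(x)
  p <- clamp((x - csf) / (cord - csf), 0, 1)
  if (binary) p <- (p >= 0.5) * 1
  cord_mask(p, img$spacing)
}

#' Write a phantom pair to disk
#'
#' Writes the four NIfTI volumes (`baseline.nii.gz`, `baseline_mask.nii.gz`,
#' `followup.nii.gz`, `followup_mask.nii.gz`) and a `truth.json` sidecar.
#'
#' @param pair A `phantom_pair` from [make_phantom_pair()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "phantom_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(pair$baseline$image, file.path(dir, "baseline.nii.gz"))
  write_volume(pair$baseline$mask, file.path(dir, "baseline_mask.nii.gz"))
  write_volume(pair$followup$image, file.path(dir, "followup.nii.gz"))
  write_volume(pair$followup$mask, file.path(dir, "followup_mask.nii.gz"))
  truth <- pair$truth
  truth$centerline <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
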