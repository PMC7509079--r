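#' Extract the cord centerline from a mask
#'
#' One point per nonzero axial slice: the probability-weighted in-plane
#' centroid of the mask, smoothed along the cord axis with a low-order
#' smoothing spline, returned in world millimetres together with its
#' arc-length parameterization. The nonzero slices must form a contiguous
#' range.
#'
#' @param mask A [cord_mask()].
#' @param spline_df Effective degrees of freedom of the axial smoothing
#'   spline (capped by the number of slices).
#' @return An object of class `centerline`: `points` (n x 3 matrix, mm),
#'   `arclength` (mm, strictly increasing), `slices` (axial indices).
#' @export
extract_centerline <- function(mask, spline_df = 8) {
  stopifnot(inherits(mask, "cord_mask"))
  d <- dim(mask$data)
  wsum <- apply(mask$data, 3, sum)
  nz <- which(wsum > 0)
  if (!length(nz)) stop_input("extract_centerline: mask is empty")
  rng <- nz[1]:nz[length(nz)]
  gap <- setdiff(rng, nz)
  if (length(gap))
    stop_input("extract_centerline: mask not contiguous, empty slice at %d",
               gap[1])

  xs <- (seq_len(d[1]) - 1) * mask$spacing[1]
  ys <- (seq_len(d[2]) - 1) * mask$spacing[2]
  cx <- cy <- numeric(length(nz))
  for (i in seq_along(nz)) {
    sl <- mask$data[, , nz[i]]
    cx[i] <- sum(rowSums(sl) * xs) / wsum[nz[i]]
    cy[i] <- sum(colSums(sl) * ys) / wsum[nz[i]]
  }
  z <- (nz - 1) * mask$spacing[3]

  n <- length(nz)
  if (n >= 5) {
    df <- max(2, min(spline_df, n - 1))
    cx <- predict(smooth.spline(z, cx, df = df), z)$y
    cy <- predict(smooth.spline(z, cy, df = df), z)$y
  }
  pts <- cbind(x = cx, y = cy, z = z)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  structure(list(points = pts, arclength = arc, slices = nz),
            class = "centerline")
}

# Linear interpolation of centerline position at arc lengths `s`.
centerline_at <- function(cl, s) {
  cbind(approx(cl$arclength, cl$points[, 1], s, rule = 2)$y,
        approx(cl$arclength, cl$points[, 2], s, rule = 2)$y,
        approx(cl$arclength, cl$points[, 3], s, rule = 2)$y)
}

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

# Tangents (central differences) and a rotation-minimizing normal frame
# along positions `p` (k x 3). Returns list(t, n1, n2), each k x 3.
centerline_frames <- function(p) {
  k <- nrow(p)
  t <- rbind(p[2, ] - p[1, ],
             p[3:k, , drop = FALSE] - p[1:(k - 2), , drop = FALSE],
             p[k, ] - p[k - 1, ])
  t <- normalize_rows(t)
  ref <- if (abs(t[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- matrix(0, k, 3)
  v <- ref - sum(ref * t[1, ]) * t[1, ]
  n1[1, ] <- v / sqrt(sum(v^2))
  for (i in 2:k) {
    v <- n1[i - 1, ] - sum(n1[i - 1, ] * t[i, ]) * t[i, ]
    n1[i, ] <- v / sqrt(sum(v^2))
  }
  n2 <- cbind(t[, 2] * n1[, 3] - t[, 3] * n1[, 2],
              t[, 3] * n1[, 1] - t[, 1] * n1[, 3],
              t[, 1] * n1[, 2] - t[, 2] * n1[, 1])
  list(t = t, n1 = n1, n2 = n2)
}

#' Straighten a cord volume along its centerline
#'
#' Resamples planes perpendicular to the centerline onto a regular grid
#' whose third axis follows the straightened cord: output slice `k` lies at
#' arc length `(k-1) * step`, with in-plane axes from a rotation-minimizing
#' frame (no axial twist), in-plane spacing equal to the input in-plane
#' spacing and `step` defaulting to the mean centerline point spacing.
#' Intensities and the mask are carried through the same trilinear warp.
#'
#' @param img An [image_volume()].
#' @param mask The matching [cord_mask()].
#' @param cl A [centerline()] from [extract_centerline()]; extracted from
#'   `mask` when `NULL`.
#' @param n_slices Number of output slices; defaults to the arc length
#'   divided by the step.
#' @return A list of class `straightened`: `image`, `mask`, `step`,
#'   `centerline`.
#' @export
straighten <- function(img, mask, cl = NULL, n_slices = NULL) {
  stopifnot(inherits(img, "image_volume"), inherits(mask, "cord_mask"))
  if (!same_grid(img, mask))
    stop_input("straighten: image and mask grids differ")
  if (is.null(cl)) cl <- extract_centerline(mask)
  d <- dim(img$data)
  sp <- img$spacing

  step <- mean(diff(cl$arclength))
  if (is.null(n_slices))
    n_slices <- floor(cl$arclength[length(cl$arclength)] / step + 1e-9) + 1L
  s_out <- (seq_len(n_slices) - 1) * step
  centers <- centerline_at(cl, s_out)
  fr <- centerline_frames(centers)

  # curvature guard: perpendicular planes must not fold within the in-plane
  # field of view
  if (n_slices >= 3) {
    dd <- diff(fr$t)
    kappa <- sqrt(rowSums(dd^2)) / step
    fov <- max((d[1] - 1) * sp[1], (d[2] - 1) * sp[2]) / 2
    if (any(kappa > 1 / fov))
      stop_input(paste0("straighten: geometry error - curvature radius ",
                        "%.1f mm smaller than in-plane field of view %.1f mm"),
                 1 / max(kappa), fov)
  }

  nx <- d[1]; ny <- d[2]
  u <- (seq_len(nx) - (nx + 1) / 2) * sp[1]
  v <- (seq_len(ny) - (ny + 1) / 2) * sp[2]
  npts <- nx * ny
  uu <- rep(u, times = ny)
  vv <- rep(v, each = nx)
  pts <- matrix(0, npts * n_slices, 3)
  for (k in seq_len(n_slices)) {
    idx <- ((k - 1) * npts + 1):(k * npts)
    for (ax in 1:3)
      pts[idx, ax] <- centers[k, ax] + uu * fr$n1[k, ax] + vv * fr$n2[k, ax]
  }

  # clamp the axial coordinate at the grid faces (edge replication along z
  # only): perpendicular planes near the volume ends tilt slightly past the
  # first/last slice for a curved cord, and zero-filling there would bite
  # chunks out of a cord that in truth continues through the face
  pts[, 3] <- clamp(pts[, 3], 0, (d[3] - 1) * sp[3])

  out_sp <- c(sp[1], sp[2], step)
  im <- array(interp_world(img, pts, fill = 0), c(nx, ny, n_slices))
  mk <- array(interp_world(mask, pts, fill = 0), c(nx, ny, n_slices))
  structure(list(image = image_volume(im, out_sp),
                 mask = cord_mask(clamp(mk, 0, 1), out_sp),
                 step = step, centerline = cl),
            class = "straightened")
}
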