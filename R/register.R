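#' 9 degrees-of-freedom affine transform
#'
#' Translation (mm), rotation (radians) and shear (unitless), three of each
#' -- deliberately *no* scale component, which would absorb the very atrophy
#' signal being measured. The linear part is composed as
#' `A = Rz(rz) %*% Ry(ry) %*% Rx(rx) %*% S`, with `S` the unit-diagonal
#' upper-triangular shear matrix `[1 sxy sxz; 0 1 syz; 0 0 1]`, so
#' `det(A) = 1` exactly. The transform maps world-mm points as
#' `y = A x + t`.
#'
#' @param translation,rotation,shear Numeric length-3 vectors.
#' @return An object of class `affine9` with element `par`
#'   (`tx ty tz rx ry rz sxy sxz syz`).
#' @export
affine9 <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                    shear = c(0, 0, 0)) {
  par <- as.numeric(c(translation, rotation, shear))
  if (length(par) != 9L || any(!is.finite(par)))
    stop_input("affine9: need 9 finite parameters")
  names(par) <- c("tx", "ty", "tz", "rx", "ry", "rz", "sxy", "sxz", "syz")
  structure(list(par = par), class = "affine9")
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Homogeneous 4x4 matrix of an `affine9` (world mm)
#' @param t9 An [affine9()] (or a 9-vector).
#' @return 4x4 matrix.
#' @export
affine_matrix <- function(t9) {
  p <- if (inherits(t9, "affine9")) t9$par else as.numeric(t9)
  S <- matrix(c(1, 0, 0, p[7], 1, 0, p[8], p[9], 1), 3, 3)
  A <- rot_z(p[6]) %*% rot_y(p[5]) %*% rot_x(p[4]) %*% S
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- p[1:3]
  M
}

#' Decompose a rigid+shear homogeneous matrix into 9 parameters
#'
#' QR-based: the linear part is factored as rotation times unit-diagonal
#' upper-triangular shear. Valid when the matrix carries no scale (diagonal
#' of the triangular factor close to 1); a deviation larger than `tol`
#' errors.
#'
#' @param M 4x4 homogeneous matrix.
#' @param tol Allowed deviation of the triangular diagonal from 1.
#' @return An [affine9()].
#' @export
affine9_from_matrix <- function(M, tol = 1e-3) {
  A <- M[1:3, 1:3]
  qrd <- qr(A)
  Q <- qr.Q(qrd); U <- qr.R(qrd)
  sgn <- sign(diag(U)); sgn[sgn == 0] <- 1
  Q <- Q %*% diag(sgn); U <- diag(sgn) %*% U
  if (max(abs(diag(U) - 1)) > tol)
    stop_input("affine9_from_matrix: matrix has scale (diag %s)",
               paste(sprintf("%.4f", diag(U)), collapse = ", "))
  ry <- asin(clamp(-Q[3, 1], -1, 1))
  rx <- atan2(Q[3, 2], Q[3, 3])
  rz <- atan2(Q[2, 1], Q[1, 1])
  affine9(translation = M[1:3, 4], rotation = c(rx, ry, rz),
          shear = c(U[1, 2] / U[1, 1], U[1, 3] / U[1, 1], U[2, 3] / U[2, 2]))
}

#' @export
print.affine9 <- function(x, ...) {
  cat("<affine9> t =", sprintf("%.3f", x$par[1:3]), "mm; r =",
      sprintf("%.4f", x$par[4:6]), "rad; shear =",
      sprintf("%.4f", x$par[7:9]), "\n")
  invisible(x)
}

#' Principal square root of a homogeneous affine matrix
#'
#' Denman-Beavers iteration; the principal root is the standard halfway-space
#' construction (applying it twice reproduces the full transform).
#'
#' @param M 4x4 matrix with no nonpositive real eigenvalues.
#' @param tol Convergence tolerance on `X %*% X - M`.
#' @param maxit Iteration cap.
#' @return 4x4 matrix square root.
#' @export
sqrtm_affine <- function(M, tol = 1e-12, maxit = 100) {
  X <- M; Y <- diag(nrow(M))
  for (i in seq_len(maxit)) {
    Xn <- (X + solve(Y)) / 2
    Yn <- (Y + solve(X)) / 2
    if (max(abs(Xn - X)) < tol) return(Xn)
    X <- Xn; Y <- Yn
  }
  if (max(abs(X %*% X - M)) > 1e-8)
    stop_input("sqrtm_affine: square-root iteration did not converge")
  X
}

# Matrix in continuous 0-based voxel coordinates that samples `src` at
# world transform M applied to the grid of `dst`: vox_src = f(vox_dst).
vox_sampling_matrix <- function(M, src_spacing, dst_spacing) {
  A <- M[1:3, 1:3]; t <- M[1:3, 4]
  out <- cbind(diag(1 / src_spacing) %*% A %*% diag(dst_spacing),
               t / src_spacing)
  out
}

# Resample volume `src` onto the grid (dim_out, spacing_out) through world
# transform M (sampling position: M %*% world_coord_of_output_voxel).
resample_world <- function(src, M, dim_out = dim(src$data),
                           spacing_out = src$spacing, fill = 0) {
  Mvox <- vox_sampling_matrix(M, src$spacing, spacing_out)
  arr <- .resample_affine(as.numeric(src$data), dim(src$data),
                          as.integer(dim_out), Mvox, fill)
  image_volume(arr, spacing_out)
}

block_downsample <- function(vol, f) {
  if (f == 1L) return(vol)
  d <- dim(vol$data)
  dn <- pmax(d %/% f, 1L)
  a <- vol$data[seq_len(dn[1] * f), seq_len(dn[2] * f), seq_len(dn[3] * f),
                drop = FALSE]
  dim(a) <- c(f, dn[1], f, dn[2], f, dn[3])
  out <- apply(a, c(2, 4, 6), mean)
  image_volume(out, vol$spacing * f)
}

robust_normalize <- function(img, mask = NULL) {
  x <- img$data
  ref <- if (!is.null(mask)) median(x[mask$data > 0.5])
  else median(x[x > mean(x)])
  if (!is.finite(ref) || ref <= 0)
    stop_input("registration: cannot normalize intensities (reference %.3g)",
               ref)
  image_volume(x / ref, img$spacing)
}

# Symmetric MSD. A voxel that maps outside the other image is charged the
# squared difference between its value and the other image's mean intensity
# (the mismatch of matching nothing): averaging over the valid overlap only
# would reward degenerate transforms that shrink it, while a flat variance
# charge would bias translations toward zero on empty backgrounds.
# Matrix for parameters whose rotation/shear act about world point `ctr`
# (decoupling them from translation); the linear part is unchanged, only
# the effective translation moves: t_origin = t + ctr - A %*% ctr.
centered_matrix <- function(par, ctr) {
  M <- affine_matrix(par)
  M[1:3, 4] <- M[1:3, 4] + ctr - M[1:3, 1:3] %*% ctr
  M
}

sym_cost <- function(par, fixed, moving, mu_f, mu_m, ctr) {
  M <- centered_matrix(par, ctr)
  Minv <- solve(M)
  fwd <- resample_world(moving, M, dim(fixed$data), fixed$spacing,
                        fill = NA_real_)
  bwd <- resample_world(fixed, Minv, dim(moving$data), moving$spacing,
                        fill = NA_real_)
  half_cost <- function(ref, warped, mu_other) {
    d2 <- (ref - warped)^2
    oob <- is.na(d2)
    (sum(d2[!oob]) + sum((ref[oob] - mu_other)^2)) / length(d2)
  }
  (half_cost(fixed$data, fwd$data, mu_m) +
      half_cost(moving$data, bwd$data, mu_f)) / 2
}

#' Symmetric inverse-consistent 9-DOF affine registration
#'
#' Estimates translation, rotation and shear (no scale) between two volumes
#' by minimizing the symmetric mean-squared intensity difference -- computed
#' in both directions (moving resampled onto the fixed grid through `T`, and
#' fixed onto the moving grid through `T^-1`) and averaged -- after
#' median-of-cord intensity normalization. Deterministic: identity start,
#' three-level multi-resolution schedule (4x, 2x, 1x block-mean
#' downsampling), BFGS with fixed tolerances. The recovered transform maps
#' fixed-image world coordinates to the corresponding moving-image
#' coordinates (`moving(T(x)) ~ fixed(x)`).
#'
#' @param fixed,moving [image_volume()]s with overlapping fields of view.
#' @param mask_fixed,mask_moving Optional [cord_mask()]s used for intensity
#'   normalization (median cord intensity); otherwise a robust foreground
#'   median is used.
#' @param levels Downsampling factors, coarse to fine.
#' @param tol Relative convergence tolerance of the optimizer.
#' @param maxit Iteration cap per level.
#' @return An [affine9()] with attributes `residual` (final symmetric MSD)
#'   and `converged`.
#' @export
register_affine9 <- function(fixed, moving,
                             mask_fixed = NULL, mask_moving = NULL,
                             levels = c(4L, 2L, 1L),
                             tol = 1e-6, maxit = 300) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  f0 <- robust_normalize(fixed, mask_fixed)
  m0 <- robust_normalize(moving, mask_moving)

  # rotations/shears act about the fixed-volume centre during optimization:
  # about the world origin they would mimic translations at the object and
  # condition the problem badly
  ctr <- (dim(fixed$data) - 1) / 2 * fixed$spacing

  par <- rep(0, 9)
  parscale <- c(1, 1, 1, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02)
  res <- NULL
  for (lv in levels) {
    f <- block_downsample(f0, as.integer(lv))
    m <- block_downsample(m0, as.integer(lv))
    res <- optim(par, sym_cost, fixed = f, moving = m,
                 mu_f = mean(f$data), mu_m = mean(m$data), ctr = ctr,
                 method = "BFGS",
                 control = list(maxit = maxit, reltol = tol,
                                parscale = parscale))
    par <- res$par
  }
  # a residual at interpolation-noise level is numerically exact alignment
  # even when BFGS exhausts its iterations polishing it
  if (res$convergence != 0 && res$value > 1e-6)
    stop_input("register_affine9: did not converge (code %d, residual %.3g)",
               res$convergence, res$value)
  # back to the origin convention: same linear part, shifted translation
  M <- centered_matrix(par, ctr)
  out <- affine9(M[1:3, 4], par[4:6], par[7:9])
  attr(out, "residual") <- res$value
  attr(out, "converged") <- TRUE
  out
}

#' Serialize / load an `affine9` transform as JSON
#'
#' The file carries the 9 named parameters, the composition convention and
#' the 4x4 world matrix for interoperability.
#'
#' @param t9 An [affine9()].
#' @param path JSON path.
#' @return `path` (write) or an [affine9()] (read).
#' @export
write_affine9 <- function(t9, path) {
  stopifnot(inherits(t9, "affine9"))
  jsonlite::write_json(list(
    parameters = as.list(t9$par),
    convention = "y = Rz Ry Rx Shear x + t; world mm; no scale (det = 1)",
    matrix = affine_matrix(t9)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine9
#' @export
read_affine9 <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- unlist(obj$parameters)
  affine9(p[1:3], p[4:6], p[7:9])
}

#' Resample a baseline/follow-up pair into the halfway space
#'
#' Computes the principal square root `H` of the full transform and warps
#' each member half-way: the baseline is sampled through `H^-1` and the
#' follow-up through `H` (its inverse-direction half), onto a common grid,
#' with masks carried by the same warps. Both members pass through exactly
#' one identical interpolation step, differing only in which half transform
#' they receive, so no processing bias is introduced between timepoints.
#'
#' @param baseline,followup Lists with elements `image` and `mask` on their
#'   own grids.
#' @param t9 An [affine9()] (or 4x4 matrix) from
#'   `register_affine9(fixed = baseline, moving = followup)`.
#' @param dim_out,spacing_out Halfway grid; defaults to the baseline grid.
#' @return A list of class `halfway_pair`: `baseline`, `followup` (each
#'   `list(image, mask)`), `transform` (full 4x4), `half` (4x4), `spacing`.
#' @export
resample_halfway <- function(baseline, followup, t9,
                             dim_out = NULL, spacing_out = NULL) {
  M <- if (inherits(t9, "affine9")) affine_matrix(t9) else t9
  if (is.null(dim_out)) dim_out <- dim(baseline$image$data)
  if (is.null(spacing_out)) spacing_out <- baseline$image$spacing
  H <- sqrtm_affine(M)
  Hinv <- solve(H)

  warp_member <- function(member, half) {
    img <- resample_world(member$image, half, dim_out, spacing_out, fill = 0)
    mk <- resample_world(member$mask, half, dim_out, spacing_out, fill = 0)
    list(image = img,
         mask = cord_mask(clamp(mk$data, 0, 1), spacing_out))
  }

  structure(list(baseline = warp_member(baseline, Hinv),
                 followup = warp_member(followup, H),
                 transform = M, half = H, spacing = spacing_out),
            class = "halfway_pair")
}
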