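# Shift-based grey-value morphology.
#
# The boundary-shift region and the CSF ring are defined through one- and
# two-voxel dilations/erosions with box structuring elements (3x3 in-plane,
# 3x3x3 in 3-D). These are realized as running max/min filters over integer
# shifts of the array; out-of-bounds neighbours take the filter's neutral
# element (0 for dilation, and for erosion the border is padded with the edge
# behaviour documented per function).

shift_array3 <- function(a, dx, dy, dz, fill) {
  d <- dim(a)
  out <- array(fill, d)
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
  out
}

# Grey dilation (max filter) over the 3x3x3 neighbourhood.
dilate3d_1 <- function(a) {
  out <- a
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- pmax(out, shift_array3(a, dx, dy, dz, 0))
  }
  out
}

# Grey erosion (min filter) over the 3x3x3 neighbourhood. Outside the grid
# the probability map is taken as 0, so the object erodes at the borders.
erode3d_1 <- function(a) {
  out <- a
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- pmin(out, shift_array3(a, dx, dy, dz, 0))
  }
  out
}

shift_matrix <- function(m, dx, dy, fill) {
  d <- dim(m)
  out <- matrix(fill, d[1], d[2])
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  out[xs, ys] <- m[xs - dx, ys - dy]
  out
}

# Binary 2-D dilation with the 3x3 square (8-connected) element; the grid
# border clips the result (no padding beyond the image).
dilate2d_1 <- function(m) {
  out <- m
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    out <- pmax(out, shift_matrix(m, dx, dy, 0))
  }
  out
}

# 3x3x3 box mean filter (edge-replicated denominator: borders average over
# the in-grid neighbours only).
boxmean3d_1 <- function(a) {
  acc <- array(0, dim(a))
  cnt <- array(0, dim(a))
  ones <- array(1, dim(a))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    acc <- acc + shift_array3(a, dx, dy, dz, 0)
    cnt <- cnt + shift_array3(ones, dx, dy, dz, 0)
  }
  acc / cnt
}
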