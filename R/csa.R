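#' Cord level range on the straightened axis
#'
#' A half-open window of axial slice indices (1-based, `start` inclusive,
#' `end` exclusive) on the straightened cord axis, labelled with the
#' vertebral level it stands for (`C1-2`, `C2-5`, or custom). Vertebral
#' labelling itself is outside this package: ranges are user-supplied (or
#' defined by construction for phantoms).
#'
#' @param start,end Slice window, `1 <= start < end`.
#' @param label Level label.
#' @return An object of class `level_range`.
#' @export
level_range <- function(start, end, label = "custom") {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || start >= end)
    stop_input("level_range: need 1 <= start < end (got %d, %d)", start, end)
  structure(list(start = start, end = end, label = label),
            class = "level_range")
}

lr_slices <- function(lr, nz) {
  if (lr$end > nz + 1L)
    stop_input("level_range %s: end %d exceeds mask extent (%d slices)",
               lr$label, lr$end, nz)
  seq.int(lr$start, lr$end - 1L)
}

#' Per-slice cross-sectional areas
#'
#' Area of each axial slice in the range, computed as the sum of mask
#' probabilities times the in-plane voxel area, so probabilistic
#' (partial-volume) masks contribute fractional area.
#'
#' @param mask A [cord_mask()] (normally straightened, so slices are
#'   perpendicular to the cord).
#' @param lr A [level_range()]; `NULL` uses the full extent.
#' @return Numeric vector of slice areas (mm^2).
#' @export
slice_areas <- function(mask, lr = NULL) {
  stopifnot(inherits(mask, "cord_mask"))
  nz <- dim(mask$data)[3]
  if (is.null(lr)) lr <- level_range(1L, nz + 1L, "full")
  sl <- lr_slices(lr, nz)
  pxarea <- mask$spacing[1] * mask$spacing[2]
  areas <- apply(mask$data[, , sl, drop = FALSE], 3, sum) * pxarea
  if (any(areas == 0))
    stop_input("slice_areas: empty mask slice at index %d",
               sl[which(areas == 0)[1]])
  areas
}

#' Mean cross-sectional area over a level range
#'
#' The CSA (or MUCCA-style) summary: arithmetic mean of the per-slice areas.
#'
#' @inheritParams slice_areas
#' @return Mean area (mm^2).
#' @export
mean_csa <- function(mask, lr = NULL) {
  mean(slice_areas(mask, lr))
}

#' Percent change between two area (or volume) measurements
#'
#' `100 * (followup - baseline) / baseline`; negative values denote atrophy.
#' The result is invariant to a common rescaling of both inputs.
#'
#' @param baseline,followup Measurements in the same units; `baseline > 0`.
#' @return Percent change.
#' @export
percent_change <- function(baseline, followup) {
  if (any(baseline <= 0))
    stop_input("percent_change: baseline must be positive")
  100 * (followup - baseline) / baseline
}
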