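# Threshold-based metabolic tumor segmentation and perimeter extraction.
#
# The metabolically active lesion is the 26-connected (vertex-adjacent)
# component of the voxels with SUV >= fraction * SUV(hotspot) that contains
# the hotspot. The tumor boundary is the outermost layer of mask voxels:
# those with at least one of their 6 face-adjacent neighbors outside the
# mask (the grid border counts as outside). The 26/6 pairing keeps the body
# and boundary definitions morphologically consistent. No hole filling or
# minimum-size filtering is applied; interior holes contribute perimeter
# voxels.

#' Segment the metabolic tumor volume around a hotspot
#'
#' Thresholds the volume at `threshold_fraction * SUV(hotspot)` (inclusive:
#' SUV >= threshold) and keeps the 26-connected component containing the
#' hotspot. An optional search bounding box restricts the component so a
#' second avid structure cannot be captured.
#'
#' @param volume a [pet_volume()].
#' @param hotspot 0-based voxel index `c(i, j, k)`; defaults to
#'   [find_hotspot()] over the whole volume.
#' @param threshold_fraction fraction of the hotspot SUV used as the
#'   absolute threshold, in (0, 1); default 0.40.
#' @param search_mask optional logical array limiting the eligible voxels.
#' @return A `tumor_segmentation` object: `mask` (logical array),
#'   `hotspot`, `threshold_suv`, `perimeter` (0-based n x 3 index matrix)
#'   and `perimeter_mask` (logical array).
#' @export
segment_tumor <- function(volume, hotspot = NULL, threshold_fraction = 0.40,
                          search_mask = NULL) {
  stopifnot(inherits(volume, "pet_volume"))
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      threshold_fraction <= 0 || threshold_fraction >= 1)
    stop_invalid("'threshold_fraction' must lie in (0, 1)")
  if (is.null(hotspot)) hotspot <- find_hotspot(volume, search_mask)
  hotspot <- as.integer(hotspot)
  dm <- volume$shape
  if (length(hotspot) != 3L || any(hotspot < 0L) || any(hotspot >= dm))
    stop_invalid("'hotspot' out of bounds for the volume")
  hs_suv <- volume$values[hotspot[1] + 1L, hotspot[2] + 1L, hotspot[3] + 1L]
  if (hs_suv <= 0)
    stop_invalid("degenerate lesion: hotspot SUV must be > 0")
  thr <- threshold_fraction * hs_suv
  eligible <- volume$values >= thr
  if (!is.null(search_mask)) {
    if (!identical(dim(search_mask), dm))
      stop_invalid("'search_mask' must have the same shape as the volume")
    eligible <- eligible & search_mask
  }
  mask <- connected_component26(eligible, hotspot)
  pmask <- perimeter_mask6(mask)
  structure(list(mask = mask,
                 hotspot = hotspot,
                 threshold_suv = thr,
                 perimeter = which_voxels0(pmask),
                 perimeter_mask = pmask),
            class = "tumor_segmentation")
}

#' @export
print.tumor_segmentation <- function(x, ...) {
  cat(sprintf("<tumor_segmentation> %d voxels, threshold SUV %.4g, hotspot (%d,%d,%d), %d perimeter voxels\n",
              sum(x$mask), x$threshold_suv,
              x$hotspot[1], x$hotspot[2], x$hotspot[3], nrow(x$perimeter)))
  invisible(x)
}

# 26-connected component of `eligible` containing `seed0` (0-based),
# grown by vectorized dilation restricted to the eligible set.
connected_component26 <- function(eligible, seed0) {
  comp <- array(FALSE, dim(eligible))
  comp[seed0[1] + 1L, seed0[2] + 1L, seed0[3] + 1L] <- TRUE
  offs <- offsets26()
  repeat {
    grown <- comp
    for (r in seq_len(nrow(offs)))
      grown <- grown | shift3(comp, offs[r, ])
    grown <- grown & eligible
    grown <- grown | comp
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

# Mask voxels with >= 1 face-adjacent (6-neighborhood) neighbor outside the
# mask; out-of-grid counts as outside.
perimeter_mask6 <- function(mask) {
  offs <- offsets6()
  inside_all <- array(TRUE, dim(mask))
  for (r in seq_len(nrow(offs)))
    inside_all <- inside_all & shift3(mask, offs[r, ], fill = FALSE)
  mask & !inside_all
}

#' Extract the perimeter (outermost voxel layer) of a binary mask
#'
#' @param mask logical 3D array with at least one `TRUE` voxel.
#' @return 0-based n x 3 integer matrix of perimeter voxel indices.
#' @export
extract_perimeter <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop_invalid("'mask' must be a 3D array")
  mask <- mask != 0
  if (!any(mask)) stop_invalid("empty mask")
  which_voxels0(perimeter_mask6(mask))
}
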