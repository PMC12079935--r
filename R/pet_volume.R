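# PET volume container, isotropic resampling, hotspot location.
#
# Coordinate convention used throughout the package: voxel indices are
# 0-based triples (i, j, k); the physical center of voxel (i, j, k) sits at
# (i*sx, j*sy, k*sz) in mm. All distances are measured between voxel
# centers in mm.

#' Construct a PET SUV volume
#'
#' A `pet_volume` holds a 3D array of standardized uptake values (SUV,
#' dimensionless, body-weight normalized) plus the voxel edge lengths in
#' mm. SUV maps are assumed already computed; decay/dose conversion is out
#' of scope.
#'
#' @param values 3D numeric array of SUV; all values must be finite and
#'   non-negative.
#' @param spacing numeric triple of voxel edge lengths in mm (strictly
#'   positive). A scalar is recycled to the three axes.
#' @return An object of class `pet_volume` with fields `values`, `spacing`
#'   and `shape`.
#' @examples
#' v <- pet_volume(array(1, c(4, 4, 4)), spacing = 3)
#' v$shape
#' @export
pet_volume <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_invalid("'values' must be a 3D array")
  if (any(dim(values) < 1L))
    stop_invalid("empty volume: all dimensions must be >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop_invalid("'spacing' must be a strictly positive triple (mm)")
  if (!all(is.finite(values)))
    stop_invalid("all SUV values must be finite")
  if (any(values < 0))
    stop_invalid("all SUV values must be >= 0")
  structure(list(values = values, spacing = spacing, shape = dim(values)),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  SUV range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Resample a PET volume to an isotropic grid
#'
#' Trilinear interpolation at the new voxel centers. The physical extent of
#' the grid is preserved to within one voxel and the origin (center of voxel
#' (0,0,0)) is unchanged. Output SUV is clipped at 0. When the input is
#' already at the target spacing the volume is returned unchanged.
#'
#' @param volume a [pet_volume()].
#' @param target_spacing_mm isotropic target voxel edge, mm (default 3.0,
#'   the spacing at which all downstream metrics are defined).
#' @return A `pet_volume` with spacing `c(t, t, t)`.
#' @export
resample_isotropic <- function(volume, target_spacing_mm = 3.0) {
  stopifnot(inherits(volume, "pet_volume"))
  t <- as.numeric(target_spacing_mm)
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    stop_invalid("'target_spacing_mm' must be a single positive number")
  s <- volume$spacing
  if (all(abs(s - t) < 1e-12)) return(volume)
  dm <- volume$shape
  a <- volume$values
  for (ax in 1:3) {
    n <- dim(a)[ax]
    extent <- (n - 1) * s[ax]
    n_new <- max(1L, as.integer(floor(extent / t + 1e-9)) + 1L)
    # fractional source index of each new voxel center along this axis
    f <- (seq_len(n_new) - 1) * t / s[ax]
    lo <- pmin(floor(f), n - 1)        # 0-based lower sample
    w <- f - lo
    lo1 <- as.integer(lo) + 1L         # 1-based
    hi1 <- pmin(lo1 + 1L, n)
    take <- function(idx) switch(ax,
                                 a[idx, , , drop = FALSE],
                                 a[, idx, , drop = FALSE],
                                 a[, , idx, drop = FALSE])
    a_lo <- take(lo1); a_hi <- take(hi1)
    wb <- switch(ax,
                 array(w, c(n_new, dim(a)[2], dim(a)[3])),
                 aperm(array(w, c(n_new, dim(a)[1], dim(a)[3])), c(2, 1, 3)),
                 aperm(array(w, c(n_new, dim(a)[1], dim(a)[2])), c(2, 3, 1)))
    a <- a_lo * (1 - wb) + a_hi * wb
  }
  pet_volume(pmax(a, 0), rep(t, 3L))
}

#' Locate the SUVmax voxel (hotspot)
#'
#' Returns the 0-based index of the voxel with maximum SUV over the search
#' region (whole volume, or `search_mask` when given). Ties are broken by
#' the lexicographically smallest (i, j, k) so results are deterministic.
#'
#' @param volume a [pet_volume()].
#' @param search_mask optional logical array of the same shape restricting
#'   the search; must contain at least one `TRUE` voxel.
#' @return Integer vector `c(i, j, k)`, 0-based.
#' @export
find_hotspot <- function(volume, search_mask = NULL) {
  stopifnot(inherits(volume, "pet_volume"))
  vals <- volume$values
  if (!is.null(search_mask)) {
    if (!identical(dim(search_mask), dim(vals)))
      stop_invalid("'search_mask' must have the same shape as the volume")
    if (!any(search_mask))
      stop_invalid("empty search region")
    v <- vals[search_mask]
    m <- max(v)
    cand <- which_voxels0(search_mask & vals == m)
  } else {
    m <- max(vals)
    cand <- which_voxels0(vals == m)
  }
  ord <- order(cand[, 1], cand[, 2], cand[, 3])
  as.integer(cand[ord[1], ])
}
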