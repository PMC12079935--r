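# Conventional and geometric PET parameters for a single segmented lesion.
#
# NHOCmax: Euclidean distance (mm) from the SUVmax voxel center to the
# tumor centroid, divided by the radius of a sphere with the tumor's
# volume. NHOPmax: minimum Euclidean distance (mm) from the SUVmax voxel
# center to the perimeter voxel centers, divided by the same radius. Both
# are dimensionless; NHOC grows and NHOP shrinks as the hotspot migrates
# toward the tumor edge.

#' Metabolic tumor volume of a binary mask
#'
#' @param mask logical 3D array (nonempty).
#' @param spacing voxel edge lengths in mm (triple or scalar).
#' @return Volume in mL (voxel count x voxel volume / 1000).
#' @export
compute_mtv <- function(mask, spacing) {
  mask <- mask != 0
  if (!any(mask)) stop_invalid("empty mask")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop_invalid("spacing must be positive")
  sum(mask) * prod(spacing) / 1000
}

#' SUVmax and SUVmean over a mask
#'
#' @param volume a [pet_volume()].
#' @param mask logical array of the same shape, nonempty.
#' @return List with `suv_max` and `suv_mean`.
#' @export
compute_suv_stats <- function(volume, mask) {
  stopifnot(inherits(volume, "pet_volume"))
  mask <- mask != 0
  if (!identical(dim(mask), dim(volume$values)))
    stop_invalid("'mask' must have the same shape as the volume")
  if (!any(mask)) stop_invalid("empty mask")
  v <- volume$values[mask]
  list(suv_max = max(v), suv_mean = mean(v))
}

#' Total lesion glycolysis
#'
#' @param suv_mean mean SUV over the lesion (>= 0).
#' @param mtv_ml metabolic tumor volume in mL (>= 0).
#' @return TLG = SUVmean x MTV, in SUV.mL.
#' @export
compute_tlg <- function(suv_mean, mtv_ml) {
  if (suv_mean < 0 || mtv_ml < 0)
    stop_invalid("'suv_mean' and 'mtv_ml' must be >= 0")
  suv_mean * mtv_ml
}

#' Tumor centroid in physical coordinates
#'
#' Unweighted geometric centroid of the mask voxel centers by default;
#' SUV-weighted centroid available behind `weights`.
#'
#' @param mask logical 3D array, nonempty.
#' @param spacing voxel edge lengths in mm.
#' @param weights optional array of the same shape (e.g. SUV) for a
#'   weighted centroid; default unweighted.
#' @return Numeric triple, mm.
#' @export
compute_centroid <- function(mask, spacing, weights = NULL) {
  mask <- mask != 0
  if (!any(mask)) stop_invalid("empty mask")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  xyz <- voxel_centers_mm(which_voxels0(mask), spacing)
  if (is.null(weights)) return(colMeans(xyz))
  w <- weights[mask]
  if (any(w < 0) || sum(w) <= 0) stop_invalid("invalid centroid weights")
  colSums(xyz * w) / sum(w)
}

#' Radius of the sphere with the tumor's volume
#'
#' @param mtv_ml tumor volume in mL (> 0).
#' @return Radius in mm: (3 x 1000 x mtv_ml / 4pi)^(1/3).
#' @export
equivalent_sphere_radius <- function(mtv_ml) {
  if (!is.finite(mtv_ml) || mtv_ml <= 0)
    stop_invalid("'mtv_ml' must be > 0")
  (3 * 1000 * mtv_ml / (4 * pi))^(1 / 3)
}

#' Normalized hotspot-to-centroid distance (NHOC)
#'
#' @param hotspot 0-based voxel index of the SUVmax voxel.
#' @param centroid_mm tumor centroid, mm.
#' @param r_equiv_mm equivalent-sphere radius, mm (> 0).
#' @param spacing voxel edge lengths, mm.
#' @return Dimensionless NHOC >= 0.
#' @export
compute_nhoc <- function(hotspot, centroid_mm, r_equiv_mm, spacing) {
  if (r_equiv_mm <= 0) stop_invalid("'r_equiv_mm' must be > 0")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  p <- as.numeric(hotspot) * spacing
  sqrt(sum((p - centroid_mm)^2)) / r_equiv_mm
}

#' Normalized hotspot-to-perimeter distance (NHOP)
#'
#' Minimum center-to-center Euclidean distance from the hotspot voxel to
#' the perimeter voxels, divided by the equivalent-sphere radius. Zero when
#' the hotspot is itself a perimeter voxel.
#'
#' @param hotspot 0-based voxel index of the SUVmax voxel.
#' @param perimeter 0-based n x 3 matrix of perimeter voxel indices.
#' @param r_equiv_mm equivalent-sphere radius, mm (> 0).
#' @param spacing voxel edge lengths, mm.
#' @return Dimensionless NHOP >= 0.
#' @export
compute_nhop <- function(hotspot, perimeter, r_equiv_mm, spacing) {
  if (r_equiv_mm <= 0) stop_invalid("'r_equiv_mm' must be > 0")
  if (is.null(dim(perimeter))) perimeter <- matrix(perimeter, ncol = 3)
  if (nrow(perimeter) == 0L) stop_invalid("empty perimeter")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d2 <- sweep(perimeter, 2, as.numeric(hotspot), `-`)
  d2 <- sweep(d2, 2, spacing, `*`)
  sqrt(min(rowSums(d2^2))) / r_equiv_mm
}

#' Extract all lesion metrics from a PET volume
#'
#' Runs the full preprocessing chain with the package defaults: resample to
#' an isotropic grid (3 mm), locate the SUVmax hotspot, segment at 40% of
#' SUVmax, extract the perimeter, and compute SUVmax, SUVmean, MTV, TLG,
#' centroid, equivalent-sphere radius, NHOCmax and NHOPmax. A degenerate
#' lesion (single voxel) yields NHOC = NHOP = 0 with a `"degenerate"` flag
#' and a warning rather than an error, so batch extraction never aborts.
#'
#' @param volume a [pet_volume()].
#' @param target_spacing_mm isotropic resampling target, mm; `NULL` or `NA`
#'   disables resampling (metrics then honor the anisotropic spacing).
#' @param threshold_fraction segmentation threshold as a fraction of
#'   SUVmax; default 0.40.
#' @param centroid_weighting `"geometric"` (default) or `"suv_weighted"`.
#' @param search_mask optional logical array (on the input grid is not
#'   supported; supply on the resampled grid) restricting hotspot search
#'   and segmentation.
#' @return A `tumor_metrics` object; see [as.data.frame.tumor_metrics()]
#'   for the serialized row schema.
#' @export
extract_metrics <- function(volume, target_spacing_mm = 3.0,
                            threshold_fraction = 0.40,
                            centroid_weighting = c("geometric", "suv_weighted"),
                            search_mask = NULL) {
  stopifnot(inherits(volume, "pet_volume"))
  centroid_weighting <- match.arg(centroid_weighting)
  suv_max_input <- max(volume$values)
  resampled <- !is.null(target_spacing_mm) && !is.na(target_spacing_mm)
  if (resampled) volume <- resample_isotropic(volume, target_spacing_mm)
  spacing <- volume$spacing

  hotspot <- find_hotspot(volume, search_mask)
  seg <- segment_tumor(volume, hotspot, threshold_fraction, search_mask)
  stats <- compute_suv_stats(volume, seg$mask)
  mtv <- compute_mtv(seg$mask, spacing)
  tlg <- compute_tlg(stats$suv_mean, mtv)
  w <- if (centroid_weighting == "suv_weighted") volume$values else NULL
  centroid <- compute_centroid(seg$mask, spacing, weights = w)
  r_eq <- equivalent_sphere_radius(mtv)

  flags <- character(0)
  if (sum(seg$mask) <= 1L) {
    flags <- c(flags, "degenerate")
    warning("degenerate lesion (<= 1 voxel): NHOC and NHOP set to 0",
            call. = FALSE)
    nhoc <- 0; nhop <- 0
  } else {
    nhoc <- compute_nhoc(hotspot, centroid, r_eq, spacing)
    nhop <- compute_nhop(hotspot, seg$perimeter, r_eq, spacing)
  }

  structure(list(
    suv_max = stats$suv_max,
    suv_mean = stats$suv_mean,
    mtv_ml = mtv,
    tlg = tlg,
    centroid_mm = centroid,
    r_equiv_mm = r_eq,
    nhoc_max = nhoc,
    nhop_max = nhop,
    hotspot = hotspot,
    segmentation = seg,
    flags = flags,
    provenance = list(
      resampled = resampled,
      target_spacing_mm = if (resampled) target_spacing_mm else NA_real_,
      threshold_fraction = threshold_fraction,
      centroid_weighting = centroid_weighting,
      suv_max_input_grid = suv_max_input,
      n_voxels = sum(seg$mask))
  ), class = "tumor_metrics")
}

#' @export
print.tumor_metrics <- function(x, ...) {
  cat("<tumor_metrics>\n")
  cat(sprintf("  SUVmax %.3f  SUVmean %.3f  MTV %.3f mL  TLG %.3f\n",
              x$suv_max, x$suv_mean, x$mtv_ml, x$tlg))
  cat(sprintf("  NHOCmax %.3f  NHOPmax %.3f  (r_equiv %.2f mm)\n",
              x$nhoc_max, x$nhop_max, x$r_equiv_mm))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}

#' One-row data frame serialization of lesion metrics
#'
#' Fixed column order used by the CSV outputs of the CLI.
#'
#' @param x a `tumor_metrics` object.
#' @param ... unused.
#' @return A one-row `data.frame`.
#' @export
as.data.frame.tumor_metrics <- function(x, ...) {
  data.frame(
    suv_max = x$suv_max, suv_mean = x$suv_mean,
    mtv_ml = x$mtv_ml, tlg = x$tlg,
    nhoc_max = x$nhoc_max, nhop_max = x$nhop_max,
    r_equiv_mm = x$r_equiv_mm,
    centroid_x_mm = x$centroid_mm[1],
    centroid_y_mm = x$centroid_mm[2],
    centroid_z_mm = x$centroid_mm[3],
    flags = paste(x$flags, collapse = ";"),
    stringsAsFactors = FALSE)
}
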