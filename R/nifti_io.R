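# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Scope: 3D volumes, scalar datatypes (uint8, int16, int32, float32,
# float64), scl_slope/scl_inter scaling, both endiannesses. The voxel grid
# is taken in stored (i, j, k) order — that storage order is the package's
# canonical orientation — and spacing comes from pixdim[1:3], assumed mm.
# Orientation matrices (qform/sform) are written for round-tripping but
# not used to reorder axes. No pre-installed R package provides NIfTI in
# this toolchain, hence this deliberately small implementation.

NIFTI_DT <- list(`2`  = list(what = "integer", size = 1, signed = FALSE),
                 `4`  = list(what = "integer", size = 2, signed = TRUE),
                 `8`  = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "numeric", size = 4, signed = TRUE),
                 `64` = list(what = "numeric", size = 8, signed = TRUE))

#' Read a 3D PET volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [pet_volume()] with spacing from the header's `pixdim`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop_invalid("corrupt NIfTI file (short header): ", path)
  endian <- .Platform$endian
  sizeof_hdr <- readBin(hdr_raw, "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- if (endian == "little") "big" else "little"
    sizeof_hdr <- readBin(hdr_raw, "integer", 1, 4, endian = endian)
    if (sizeof_hdr != 348L) stop_invalid("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop_invalid("missing NIfTI magic: ", path)
  if (magic == "ni1") stop_invalid("two-file NIfTI (.hdr/.img) not supported: ", path)
  at <- function(offset, what, n, size, signed = TRUE)
    readBin(hdr_raw[(offset + 1):348], what, n, size, signed = signed,
            endian = endian)
  dim0 <- at(40, "integer", 8, 2)
  ndim <- dim0[1]
  dims <- dim0[2:(1 + max(ndim, 1))]
  if (ndim > 3) {
    extra <- dim0[(2 + 3):(1 + ndim)]
    if (any(extra > 1))
      stop_invalid(sprintf("expected a 3D image, got %dD: ", ndim), path)
    dims <- dim0[2:4]
  }
  if (ndim < 3) stop_invalid(sprintf("expected a 3D image, got %dD: ", ndim), path)
  dims <- as.integer(dims[1:3])
  datatype <- at(70, "integer", 1, 2)
  spec <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(spec)) stop_invalid("unsupported NIfTI datatype code ", datatype)
  pixdim <- at(76, "numeric", 4, 4)[2:4]
  vox_offset <- at(108, "numeric", 1, 4)
  scl_slope <- at(112, "numeric", 1, 4)
  scl_inter <- at(116, "numeric", 1, 4)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  ntot <- prod(as.numeric(dim0[2:(1 + ndim)]))
  vals <- readBin(con, spec$what, ntot, spec$size, signed = spec$signed,
                  endian = endian)
  if (length(vals) < prod(dims)) stop_invalid("truncated NIfTI data: ", path)
  vals <- as.numeric(vals[seq_len(prod(dims))])
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  pet_volume(array(vals, dims), as.numeric(pixdim))
}

#' Write a 3D volume to a NIfTI-1 file (float32)
#'
#' @param volume a [pet_volume()] or a 3D array.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param spacing voxel spacing (mm), required when `volume` is a bare
#'   array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing = NULL) {
  if (inherits(volume, "pet_volume")) {
    a <- volume$values; sp <- volume$spacing
  } else {
    if (is.null(spacing)) stop_invalid("'spacing' required for a bare array")
    a <- volume; sp <- if (length(spacing) == 1L) rep(spacing, 3) else spacing
  }
  if (length(dim(a)) != 3L) stop_invalid("'volume' must be 3D")
  dm <- dim(a)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4)                                     # sizeof_hdr
  w(raw(36), 1)                                  # data_type..dim_info
  w(as.integer(c(3, dm, 1, 1, 1, 1)), 2)          # dim
  w(numeric(3), 4)                               # intent_p1..p3
  w(0L, 2)                                       # intent_code
  w(16L, 2)                                      # datatype float32
  w(32L, 2)                                      # bitpix
  w(0L, 2)                                       # slice_start
  w(c(1, sp, 1, 1, 1, 1), 4)                      # pixdim (qfac = 1)
  w(352, 4)                                      # vox_offset
  w(1, 4); w(0, 4)                               # scl_slope, scl_inter
  w(0L, 2); w(raw(2), 1)                         # slice_end, slice_code, xyzt_units
  w(numeric(4), 4)                               # cal_max..toffset
  w(c(0L, 0L), 4)                                # glmax, glmin
  w(raw(104), 1)                                 # descrip + aux_file
  w(c(0L, 1L), 2)                                # qform_code, sform_code
  w(numeric(6), 4)                               # quatern + qoffset
  w(c(sp[1], 0, 0, 0), 4)                        # srow_x
  w(c(0, sp[2], 0, 0), 4)                        # srow_y
  w(c(0, 0, sp[3], 0), 4)                        # srow_z
  w(raw(16), 1)                                  # intent_name
  w(c(charToRaw("n+1"), as.raw(0)), 1)           # magic
  w(raw(4), 1)                                   # extension flag
  w(as.numeric(a), 4)                            # data as float32
  invisible(path)
}
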