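#' Construct a perfusion volume
#'
#' A volume is a 3-D numeric array of rCBF-like values (scaled CBF units)
#' carrying its per-axis voxel size in millimetres. Volumes are generated
#' aligned to a common grid, so no affine beyond the voxel scaling is stored;
#' the NIfTI writer emits a diagonal RAS affine built from `voxel_size_mm`.
#'
#' @param data 3-D numeric array.
#' @param voxel_size_mm numeric length 1 or 3, per-axis voxel spacing in mm.
#' @return An `asl_volume`: the array with a `voxel_size_mm` attribute.
#' @export
asl_volume <- function(data, voxel_size_mm = c(3, 3, 3)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array", call. = FALSE)
  }
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be positive and finite", call. = FALSE)
  }
  structure(data, voxel_size_mm = voxel_size_mm, class = "asl_volume")
}

#' @export
print.asl_volume <- function(x, ...) {
  d <- dim(x)
  vs <- attr(x, "voxel_size_mm")
  cat(sprintf(
    "<asl_volume> %d x %d x %d voxels @ %g x %g x %g mm, range [%.3g, %.3g]\n",
    d[1], d[2], d[3], vs[1], vs[2], vs[3], min(x), max(x)
  ))
  invisible(x)
}

voxel_size <- function(v) {
  vs <- attr(v, "voxel_size_mm")
  if (is.null(vs)) c(3, 3, 3) else vs
}

# strip class/attrs, keep dim
vol_data <- function(v) {
  array(as.numeric(v), dim = dim(v))
}

#' Default ellipsoidal brain mask
#'
#' Deterministic stand-in for a brain mask: an axis-aligned ellipsoid centred
#' in the grid whose semi-axes are chosen so that roughly 60% of the grid
#' voxels are inside (semi-axis factor (3.6/pi)^(1/3)/2 of each dimension,
#' clipped at the grid boundary).
#'
#' @param grid_shape integer length 3.
#' @return logical 3-D array, `TRUE` inside the mask.
#' @export
ellipsoid_mask <- function(grid_shape) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  f <- (3.6 / pi)^(1 / 3) # semi-axis scale giving ~60% fill before clipping
  ctr <- (grid_shape + 1) / 2
  semi <- f * grid_shape / 2
  x <- ((seq_len(grid_shape[1]) - ctr[1]) / semi[1])^2
  y <- ((seq_len(grid_shape[2]) - ctr[2]) / semi[2])^2
  z <- ((seq_len(grid_shape[3]) - ctr[3]) / semi[3])^2
  r2 <- outer(outer(x, y, `+`), z, `+`)
  r2 <= 1
}

# ---- Minimal NIfTI-1 i/o -------------------------------------------------
# Single-file (.nii) NIfTI-1, little-endian. Only what the pipeline needs:
# 3-D volumes, float32 storage, diagonal RAS sform from voxel_size_mm.
# No R NIfTI package is available in this stack, hence the hand-written codec;
# it is cross-validated against nibabel in the test suite.

nifti_pad <- function(raw_vec, n) {
  out <- raw(n)
  if (length(raw_vec)) out[seq_along(raw_vec)] <- raw_vec[seq_len(min(n, length(raw_vec)))]
  out
}

#' Write a volume as NIfTI-1
#'
#' @param v an [asl_volume()] (or plain 3-D array).
#' @param path output file path ending in `.nii`.
#' @param descrip short description stored in the header (max 79 chars).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(v, path, descrip = "") {
  d <- dim(v)
  if (length(d) != 3L) stop("only 3-D volumes are supported", call. = FALSE)
  vs <- if (inherits(v, "asl_volume")) voxel_size(v) else c(3, 3, 3)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wr <- function(x, n) writeBin(nifti_pad(x, n), con)

  wi(348L, 4)                                   # sizeof_hdr
  wr(raw(0), 35)                                # data_type, db_name, extents, session_error, regular
  wr(as.raw(0L), 1)                             # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)               # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(16L, 2)                                    # datatype: float32
  wi(32L, 2)                                    # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, vs, 1, 1, 1, 1))                      # pixdim[8], qfac = 1
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); wr(raw(0), 1); wr(raw(0), 1)       # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                                # cal_max, cal_min, slice_duration
  wf(0)                                         # toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  wr(charToRaw(substr(descrip, 1, 79)), 80)     # descrip
  wr(raw(0), 24)                                # aux_file
  wi(0L, 2)                                     # qform_code
  wi(2L, 2)                                     # sform_code: aligned
  wf(c(0, 0, 0, 0, 0, 0))                       # quatern b,c,d + qoffset x,y,z
  wf(c(vs[1], 0, 0, 0))                         # srow_x
  wf(c(0, vs[2], 0, 0))                         # srow_y
  wf(c(0, 0, vs[3], 0))                         # srow_z
  wr(raw(0), 16)                                # intent_name
  wr(c(charToRaw("n+1"), as.raw(0L)), 4)        # magic
  wr(raw(0), 4)                                 # extension indicator
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports single-file little-endian NIfTI-1 with uint8, int16, int32,
#' float32 or float64 storage; applies `scl_slope`/`scl_inter`.
#'
#' @param path path to a `.nii` file.
#' @return an [asl_volume()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n, size = 4L) readBin(con, "numeric", n = n, size = size, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  invisible(readBin(con, "raw", n = 36))
  dims <- ri(8, 2)
  ndim <- dims[1]
  if (ndim < 3L) stop("expected a 3-D volume in ", path, call. = FALSE)
  d <- dims[2:4]
  if (ndim > 3L && any(dims[5:(1 + ndim)] > 1L)) {
    stop("expected a single 3-D volume, got ", ndim, "-D data in ", path, call. = FALSE)
  }
  rf(3)                  # intent params
  ri(1, 2)               # intent_code
  datatype <- ri(1, 2)
  ri(1, 2); ri(1, 2)     # bitpix, slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(d)
  dat <- switch(as.character(datatype),
    "2"  = readBin(con, "integer", n = n, size = 1L, signed = FALSE, endian = "little"),
    "4"  = ri(n, 2),
    "8"  = ri(n, 4),
    "16" = rf(n, 4L),
    "64" = rf(n, 8L),
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE)
  )
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    dat <- dat * scl_slope + scl_inter
  }
  asl_volume(array(as.numeric(dat), dim = d), voxel_size_mm = pixdim[2:4])
}
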