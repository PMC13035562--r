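#' Minimal NIfTI-1 volume I/O
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii` or gzip-compressed
#' `.nii.gz`). Only the subset of the format this package needs is supported:
#' 3D volumes, little- or big-endian, data types uint8/int16/int32/uint16/
#' float32/float64, with `scl_slope`/`scl_inter` applied on read. Spacing is
#' taken from `pixdim`; a missing or non-positive spacing falls back to
#' 0.75 mm isotropic with a warning, and anisotropic spacing is accepted with
#' a warning. Orientation (qform/sform) is written as a plain scaling matrix
#' and ignored on read: all downstream geometry is index-space.
#'
#' `write_volume()` stores heatmaps as float32 (round-trip error below 1e-7
#' for values in \[0, 1\]) and labelmaps/masks as int32 (round-trip exact).
#'
#' @param path Path ending in `.nii` or `.nii.gz`.
#' @param kind Expected content: `"heatmap"` (values validated to \[0, 1\]),
#'   `"labelmap"` (validated to non-negative integers) or `"mask"`.
#' @return `read_volume()` returns a [voxel_grid()]; `write_volume()` returns
#'   `path` invisibly.
#' @name nifti_io
NULL

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L, uint16 = 512L)

is_gz_path <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)

#' @rdname nifti_io
#' @export
read_volume <- function(path, kind = c("heatmap", "labelmap", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (is_gz_path(path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))

  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  if (readBin(hdr[1:4], "integer", size = 4L, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(hdr[1:4], "integer", size = 4L, endian = endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported: ", path)

  rd <- function(off, what, n, size) # off = byte offset into the header
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size, endian = endian)
  dims <- rd(40, "integer", 8, 2)
  ndim <- dims[1]
  shape <- dims[2:(1 + max(ndim, 1))]
  if (ndim > 3L) {
    if (any(shape[4:ndim] > 1L)) stop("non-3D volume (dim = ",
                                      paste(shape, collapse = "x"), "): ", path)
    shape <- shape[1:3]
  }
  if (ndim < 3L || length(shape) != 3L || any(shape < 1L))
    stop("non-3D volume in ", path)
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)

  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    warning("missing/invalid pixdim in ", basename(path),
            "; assuming 0.75 mm isotropic")
    spacing <- rep(0.75, 3)
  } else if (diff(range(spacing)) > 1e-6) {
    warning("anisotropic voxel spacing in ", basename(path), ": ",
            paste(format(spacing, digits = 4), collapse = " x "), " mm")
  }

  skip <- round(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(shape)
  vals <- switch(as.character(datatype),
    "2"   = as.double(readBin(con, "integer", n = n, size = 1L, signed = FALSE, endian = endian)),
    "4"   = as.double(readBin(con, "integer", n = n, size = 2L, endian = endian)),
    "8"   = as.double(readBin(con, "integer", n = n, size = 4L, endian = endian)),
    "16"  = readBin(con, "double", n = n, size = 4L, endian = endian),
    "64"  = readBin(con, "double", n = n, size = 8L, endian = endian),
    "512" = as.double(readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = endian)),
    stop("unsupported NIfTI datatype ", datatype, " in ", path))
  if (length(vals) < n) stop("truncated voxel data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  voxel_grid(array(vals, dim = shape), spacing_mm = spacing, kind = kind)
}

#' @rdname nifti_io
#' @param grid A [voxel_grid()] to serialise.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  shape <- dim(grid$data)
  float <- grid$kind == "heatmap"
  datatype <- if (float) NIFTI_DT$float32 else NIFTI_DT$int32
  bitpix <- 32L
  sp <- grid$spacing_mm

  con <- if (is_gz_path(path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  zeros <- function(n) writeBin(raw(n), con)

  w(348L, 4L)                          # sizeof_hdr
  zeros(35L)                           # data_type, db_name, extents, session_error, regular
  zeros(1L)                            # dim_info
  w(c(3L, as.integer(shape), 1L, 1L, 1L, 1L), 2L)  # dim[8]
  zeros(12L)                           # intent_p1..p3
  w(0L, 2L)                            # intent_code
  w(as.integer(datatype), 2L)          # datatype
  w(bitpix, 2L)                        # bitpix
  w(0L, 2L)                            # slice_start
  w(c(1, sp, 1, 1, 1, 1), 4L)          # pixdim[8]
  w(352, 4L)                           # vox_offset
  w(1, 4L); w(0, 4L)                   # scl_slope, scl_inter
  w(0L, 2L); zeros(1L)                 # slice_end, slice_code
  writeBin(as.raw(2L), con)            # xyzt_units: mm
  zeros(16L)                           # cal_max..toffset
  zeros(8L)                            # glmax, glmin
  zeros(104L)                          # descrip, aux_file
  w(0L, 2L); w(1L, 2L)                 # qform_code = 0, sform_code = 1
  w(numeric(6), 4L)                    # quatern_*, qoffset_*
  w(c(sp[1], 0, 0, 0), 4L)             # srow_x
  w(c(0, sp[2], 0, 0), 4L)             # srow_y
  w(c(0, 0, sp[3], 0), 4L)             # srow_z
  zeros(16L)                           # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  zeros(4L)                            # extension flag

  if (float) {
    w(as.numeric(grid$data), 4L)
  } else {
    w(as.integer(grid$data), 4L)
  }
  invisible(path)
}
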