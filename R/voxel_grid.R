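#' Voxel grids
#'
#' A `voxel_grid` is the common substrate for all volumetric data in biopsim:
#' a 3D array indexed `(i, j, k)` with per-axis voxel spacing in millimetres
#' and a declared mapping of array axes to anatomical directions. By
#' convention axis `k` (the third array axis) is cranio-caudal and is the
#' needle axis for simulated transperineal biopsies. All geometry is computed
#' in index space; orientation metadata from file headers is recorded but not
#' used for resampling.
#'
#' Three kinds are distinguished: `"heatmap"` (per-voxel csPCa probabilities
#' in \[0, 1\]), `"labelmap"` (non-negative integer lesion labels, 0 =
#' background) and `"mask"` (binary).
#'
#' @param data A 3D numeric/integer/logical array.
#' @param spacing_mm Voxel spacing in mm; a positive scalar (isotropic) or a
#'   length-3 vector. Default 0.75 mm isotropic, the native resolution of the
#'   heatmaps this package targets.
#' @param kind One of `"heatmap"`, `"labelmap"`, `"mask"`.
#' @param axes Length-3 character vector naming the anatomical direction of
#'   each array axis; the needle axis is the one named `"SI"`
#'   (superior-inferior, i.e. cranio-caudal).
#' @return An object of class `voxel_grid`: a list with elements `data`,
#'   `spacing_mm`, `kind`, `axes`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), kind = "heatmap")
#' voxel_volume_mm3(g)
#' @export
voxel_grid <- function(data, spacing_mm = 0.75,
                       kind = c("heatmap", "labelmap", "mask"),
                       axes = c("LR", "AP", "SI")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", paste(dim(data), collapse = "x"))
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || !all(is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be positive (scalar or length 3)")
  if (length(axes) != 3L || !"SI" %in% axes)
    stop("`axes` must name 3 directions including \"SI\" (the needle axis)")

  if (kind == "heatmap") {
    rng <- range(data)
    if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
      stop("heatmap values outside [0, 1]: range ",
           format(rng[1]), " .. ", format(rng[2]))
    if (rng[1] < 0 || rng[2] > 1) data <- pmin(pmax(data, 0), 1)  # tolerance-level clamp
    storage.mode(data) <- "double"
  } else if (kind == "labelmap") {
    if (any(data < 0) || max(abs(data - round(data))) > 1e-6)
      stop("labelmap values must be non-negative integers")
    data <- round(data)
    storage.mode(data) <- "integer"
  } else {
    if (is.logical(data)) {
      data <- array(as.integer(data), dim(data))
    } else {
      rng <- range(data)
      if (rng[1] < 0 || rng[2] > 1 || any(data != as.integer(data)))
        stop("mask values must be 0/1")
      storage.mode(data) <- "integer"
    }
  }
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 kind = kind, axes = axes),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s> %s, spacing %s mm, axes [%s]\n",
              x$kind, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing_mm, digits = 4), collapse = ", "),
              paste(x$axes, collapse = " ")))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' Volume of one voxel in cubic millimetres
#' @param grid A `voxel_grid`.
#' @return Scalar, product of the three spacings.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing_mm)

#' Convert a voxel count to cubic centimetres
#'
#' Uses the package-wide convention 1 cc = 1000 mm^3, so
#' `volume_cc = n_voxels * spacing^3 / 1000`.
#' @param n_voxels Non-negative voxel count.
#' @param grid The `voxel_grid` supplying the spacing.
#' @return Volume in cc.
#' @export
voxels_to_cc <- function(n_voxels, grid) n_voxels * voxel_volume_mm3(grid) / 1000

#' Index of the needle (cranio-caudal) axis of a grid
#' @param grid A `voxel_grid`.
#' @return Integer axis index in 1..3.
#' @export
needle_axis <- function(grid) which(grid$axes == "SI")[1]

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grids have different shapes: ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"))
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-9)
    stop("grids have different spacings")
  invisible(TRUE)
}

# internal fast constructor: trusted 0/1 content, no revalidation
as_mask_grid <- function(grid, logical_data) {
  structure(list(data = array(as.integer(logical_data), dim(grid$data)),
                 spacing_mm = grid$spacing_mm, kind = "mask", axes = grid$axes),
            class = "voxel_grid")
}
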