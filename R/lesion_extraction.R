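#' Lesion extraction settings
#'
#' Bundles the tunables of the heatmap-to-lesion step. The defaults reproduce
#' the simulated-biopsy procedure this package models: candidate lesions are
#' the connected components of the heatmap thresholded at 0.5, components
#' smaller than 0.07 cc are discarded, and at most the two largest survivors
#' are biopsied.
#'
#' @param binarization_threshold Probability cut-off in (0, 1); a voxel is
#'   foreground when its value is `>=` the threshold (inclusive). Default 0.5.
#' @param connectivity 3D connectivity for component labeling: 6, 18 or 26
#'   (default 26, the most permissive standard choice).
#' @param min_volume_cc Minimum candidate volume in cc, inclusive
#'   (default 0.07).
#' @param max_biopsied_lesions Number of largest lesions to biopsy
#'   (default 2).
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(binarization_threshold = 0.5, connectivity = 26,
                              min_volume_cc = 0.07, max_biopsied_lesions = 2L) {
  if (!is.numeric(binarization_threshold) || binarization_threshold <= 0 ||
      binarization_threshold >= 1)
    stop("binarization_threshold must be in (0, 1)")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  if (min_volume_cc < 0) stop("min_volume_cc must be non-negative")
  if (max_biopsied_lesions < 1) stop("max_biopsied_lesions must be >= 1")
  structure(list(binarization_threshold = binarization_threshold,
                 connectivity = as.integer(connectivity),
                 min_volume_cc = min_volume_cc,
                 max_biopsied_lesions = as.integer(max_biopsied_lesions)),
            class = "extraction_config")
}

#' Threshold a heatmap into a binary mask
#'
#' @param heatmap A `"heatmap"` [voxel_grid()].
#' @param threshold Cut-off in (0, 1); foreground is `value >= threshold`.
#' @return A `"mask"` `voxel_grid`.
#' @export
binarize_heatmap <- function(heatmap, threshold = 0.5) {
  stopifnot(inherits(heatmap, "voxel_grid"), heatmap$kind == "heatmap")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a scalar in (0, 1)")
  as_mask_grid(heatmap, heatmap$data >= threshold)
}

#' Extract candidate lesions from a binary mask
#'
#' Labels the 3D connected components of `mask` and returns one lesion per
#' component, ordered by decreasing volume with ties broken by the
#' lexicographically smallest centroid `(i, j, k)` and then by raster-scan
#' label, so the ordering is deterministic across platforms and input
#' permutations. `lesion_id` is 1 for the largest lesion.
#'
#' Each lesion records its linear voxel indices into the source grid, its
#' voxel count, volume in cc (`n_voxels * spacing^3 / 1000`, exactly) and
#' centroid in voxel coordinates.
#'
#' @param mask A binary `voxel_grid`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A list of `lesion` objects (empty for an empty mask).
#' @export
extract_candidate_lesions <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "voxel_grid"))
  if (mask$kind != "mask" && !all(mask$data %in% c(0L, 1L)))
    stop("mask must be binary")
  dm <- dim(mask$data)
  lab <- cc_label_3d(as.logical(mask$data), dm, as.integer(connectivity))
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0L) return(list())

  idx <- which(lab > 0L)
  labv <- lab[idx]
  counts <- tabulate(labv, nbins = ncomp)
  coords <- arrayInd(idx, dm)
  cents <- rowsum(coords, labv) / counts  # per-component mean (i, j, k)

  ord <- order(-counts, cents[, 1], cents[, 2], cents[, 3], seq_len(ncomp))
  vox_cc <- voxel_volume_mm3(mask) / 1000
  lesions <- vector("list", ncomp)
  split_idx <- split(idx, labv)
  for (r in seq_len(ncomp)) {
    comp <- ord[r]
    lesions[[r]] <- structure(list(
      lesion_id = r,
      voxel_idx = split_idx[[comp]],
      n_voxels = counts[comp],
      volume_cc = counts[comp] * vox_cc,
      centroid = as.numeric(cents[comp, ]),
      grade = NA_integer_,
      grid_dim = dm,
      spacing_mm = mask$spacing_mm,
      axes = mask$axes), class = "lesion")
  }
  lesions
}

#' @export
print.lesion <- function(x, ...) {
  cat(sprintf("<lesion %d> %.4f cc (%d voxels), centroid (%.1f, %.1f, %.1f)%s\n",
              x$lesion_id, x$volume_cc, x$n_voxels,
              x$centroid[1], x$centroid[2], x$centroid[3],
              if (is.na(x$grade)) "" else sprintf(", ISUP %d", x$grade)))
  invisible(x)
}

#' Keep lesions at or above a minimum volume
#'
#' The cut is inclusive: a lesion of exactly `min_volume_cc` is retained.
#' Input order is preserved.
#'
#' @param lesions List of `lesion` objects.
#' @param min_volume_cc Minimum volume in cc.
#' @return Filtered list.
#' @export
filter_by_volume <- function(lesions, min_volume_cc = 0.07) {
  if (min_volume_cc < 0) stop("min_volume_cc must be non-negative")
  Filter(function(l) l$volume_cc >= min_volume_cc, lesions)
}

#' Select the k largest lesions
#'
#' Ordered by decreasing volume; equal volumes are broken by the
#' lexicographically smallest centroid, then by lowest `lesion_id`, so the
#' selection is invariant under permutations of the input list.
#'
#' @param lesions List of `lesion` objects.
#' @param k Number to keep (all if fewer are available).
#' @return List of at most `k` lesions.
#' @export
select_largest <- function(lesions, k = 2L) {
  if (k < 1) stop("k must be >= 1")
  if (length(lesions) <= 1L) return(lesions)
  vol <- vapply(lesions, `[[`, numeric(1), "volume_cc")
  ci <- vapply(lesions, function(l) l$centroid[1], numeric(1))
  cj <- vapply(lesions, function(l) l$centroid[2], numeric(1))
  ck <- vapply(lesions, function(l) l$centroid[3], numeric(1))
  id <- vapply(lesions, `[[`, numeric(1), "lesion_id")
  ord <- order(-vol, ci, cj, ck, id)
  lesions[ord[seq_len(min(k, length(lesions)))]]
}

#' Full heatmap-to-biopsy-targets pipeline
#'
#' `binarize -> label components -> volume filter -> top-k`, using one
#' [extraction_config()].
#'
#' @param heatmap A `"heatmap"` [voxel_grid()].
#' @param config An [extraction_config()].
#' @return List of selected `lesion` objects.
#' @export
extract_lesions <- function(heatmap, config = extraction_config()) {
  mask <- binarize_heatmap(heatmap, config$binarization_threshold)
  cand <- extract_candidate_lesions(mask, config$connectivity)
  cand <- filter_by_volume(cand, config$min_volume_cc)
  select_largest(cand, config$max_biopsied_lesions)
}

#' Rebuild a lesion's binary mask on its source grid
#' @param lesion A `lesion`.
#' @return A `"mask"` [voxel_grid()].
#' @export
lesion_mask <- function(lesion) {
  m <- array(0L, lesion$grid_dim)
  m[lesion$voxel_idx] <- 1L
  structure(list(data = m, spacing_mm = lesion$spacing_mm, kind = "mask",
                 axes = lesion$axes), class = "voxel_grid")
}

#' Tabulate lesions for export
#' @param lesions List of `lesion` objects.
#' @param patient_id Id to stamp on each row.
#' @return data.frame with columns patient_id, lesion_id, volume_cc,
#'   centroid_i/j/k, n_voxels.
#' @export
lesion_table <- function(lesions, patient_id = NA_character_) {
  if (!length(lesions))
    return(data.frame(patient_id = character(0), lesion_id = integer(0),
                      volume_cc = numeric(0), centroid_i = numeric(0),
                      centroid_j = numeric(0), centroid_k = numeric(0),
                      n_voxels = integer(0)))
  data.frame(
    patient_id = patient_id,
    lesion_id = vapply(lesions, `[[`, numeric(1), "lesion_id"),
    volume_cc = vapply(lesions, `[[`, numeric(1), "volume_cc"),
    centroid_i = vapply(lesions, function(l) l$centroid[1], numeric(1)),
    centroid_j = vapply(lesions, function(l) l$centroid[2], numeric(1)),
    centroid_k = vapply(lesions, function(l) l$centroid[3], numeric(1)),
    n_voxels = vapply(lesions, function(l) as.integer(l$n_voxels), integer(1)))
}
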