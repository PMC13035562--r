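#' Project a lesion onto the transverse biopsy plane
#'
#' Biopsy needles are modeled as straight lines parallel to the cranio-caudal
#' axis, as in transperineal biopsies through a brachytherapy grid. A lesion's
#' footprint on the transverse plane (perpendicular to the needle) is its
#' logical-OR projection along the needle axis: in-plane pixel `(a, b)` is
#' foreground iff any voxel at `(a, b)` along the needle axis is foreground.
#'
#' @param x A binary [voxel_grid()] or a `lesion`.
#' @param needle_axis Array axis the needle travels along (1, 2 or 3).
#'   Defaults to the grid's `"SI"` axis (3 under the default axis semantics).
#' @return An object of class `footprint2d`: list with `mask` (2D logical
#'   matrix), `pixel_area_mm2` (product of the two in-plane spacings) and
#'   `plane_axes` (the retained array axes).
#' @export
project_footprint <- function(x, needle_axis = NULL) {
  if (inherits(x, "lesion")) x <- lesion_mask(x)
  stopifnot(inherits(x, "voxel_grid"))
  if (x$kind != "mask" && !all(x$data %in% c(0L, 1L)))
    stop("projection input must be binary")
  if (is.null(needle_axis)) needle_axis <- needle_axis(x)
  if (!needle_axis %in% 1:3) stop("needle_axis must be 1, 2 or 3")
  keep <- setdiff(1:3, needle_axis)
  dm <- dim(x$data)
  # move the needle axis last, flatten the plane, OR along the needle
  arr <- if (needle_axis == 3L) x$data else aperm(x$data, c(keep, needle_axis))
  m <- matrix(rowSums(matrix(arr, nrow = prod(dm[keep]))) > 0,
              nrow = dm[keep[1]], ncol = dm[keep[2]])
  structure(list(mask = m,
                 pixel_area_mm2 = prod(x$spacing_mm[keep]),
                 plane_axes = keep),
            class = "footprint2d")
}

#' @export
print.footprint2d <- function(x, ...) {
  cat(sprintf("<footprint2d> %dx%d plane, %d foreground px (%.2f mm^2 each)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$pixel_area_mm2))
  invisible(x)
}

check_same_plane <- function(a, b) {
  stopifnot(inherits(a, "footprint2d"), inherits(b, "footprint2d"))
  if (!identical(dim(a$mask), dim(b$mask)))
    stop("footprints are on different planes: ",
         paste(dim(a$mask), collapse = "x"), " vs ",
         paste(dim(b$mask), collapse = "x"))
}

#' Probability that a targeted needle hits the reference lesion
#'
#' With the needle placed uniformly at random within the predicted lesion's
#' footprint, the chance of sampling reference tissue is the overlap fraction
#' `|predicted AND reference| / |predicted|` (denominator `"predicted"`, the
#' default and the statistic the simulated-biopsy decision uses). Alternative
#' overlap statistics are available for sensitivity analyses.
#'
#' @param predicted_fp Footprint of the predicted (targeted) lesion;
#'   must be non-empty.
#' @param reference_fp Footprint of the reference target (possibly empty).
#' @param denominator One of `"predicted"`, `"reference"`, `"union"`
#'   (Jaccard) or `"dice"`.
#' @return Scalar in \[0, 1\].
#' @export
hit_probability <- function(predicted_fp, reference_fp,
                            denominator = c("predicted", "reference", "union", "dice")) {
  denominator <- match.arg(denominator)
  check_same_plane(predicted_fp, reference_fp)
  np <- sum(predicted_fp$mask)
  if (np == 0L) stop("predicted footprint is empty: hit probability undefined")
  nr <- sum(reference_fp$mask)
  ni <- sum(predicted_fp$mask & reference_fp$mask)
  switch(denominator,
         predicted = ni / np,
         reference = if (nr == 0L) 0 else ni / nr,
         union = if (np + nr - ni == 0L) 0 else ni / (np + nr - ni),
         dice = 2 * ni / (np + nr))
}

#' Monte-Carlo needle oracle for the hit probability
#'
#' Samples `n_samples` needle positions uniformly (with replacement) over the
#' predicted footprint's foreground pixels and returns the fraction that also
#' land on reference foreground. Serves as an independent stochastic check of
#' [hit_probability()] with the `"predicted"` denominator. The caller's RNG
#' state is left untouched.
#'
#' @inheritParams hit_probability
#' @param n_samples Number of simulated needles (>= 1).
#' @param seed Integer seed; same seed, same estimate.
#' @return Scalar estimate in \[0, 1\].
#' @export
monte_carlo_hit_probability <- function(predicted_fp, reference_fp,
                                        n_samples = 1e5, seed = 1L) {
  check_same_plane(predicted_fp, reference_fp)
  if (n_samples < 1) stop("n_samples must be >= 1")
  fg <- which(predicted_fp$mask)
  if (!length(fg)) stop("predicted footprint is empty: hit probability undefined")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  picks <- fg[sample.int(length(fg), n_samples, replace = TRUE)]
  mean(reference_fp$mask[picks])
}

#' Simulate one targeted biopsy
#'
#' The reference target at a given ISUP threshold is the union of all
#' reference lesions with grade `>=` the threshold; a biopsy aimed at any of
#' them counts, because detection is scored at the patient level. Both the
#' predicted lesion and the qualifying-lesion union are projected onto the
#' transverse plane and the hit probability is the footprint overlap. The
#' biopsy is positive when that probability strictly exceeds `hit_cutoff`
#' (default 0.5).
#'
#' A patient whose reference lesions are all below the threshold has an empty
#' qualifying set: the probability is 0 and the biopsy negative.
#'
#' @param predicted A non-empty `lesion` (the biopsy target).
#' @param annotation A [reference_annotation()]; must be present (calling
#'   this for a non-RP patient is a contract violation).
#' @param isup_threshold ISUP grade-group threshold (2 or 3 in the standard
#'   analysis).
#' @param needle_axis Needle axis (default: the grid's `"SI"` axis).
#' @param hit_cutoff Positivity cut-off on the hit probability; strict
#'   inequality. Default 0.5.
#' @param needle_radius_px Optional needle half-width in in-plane pixels; the
#'   predicted footprint is dilated by a square of this radius (default 0, a
#'   point needle).
#' @param denominator Overlap statistic, see [hit_probability()].
#' @param reference_fp Optional precomputed footprint of the qualifying-lesion
#'   union (as returned by [qualifying_footprint()]); avoids re-projecting the
#'   reference when many biopsies share a target.
#' @return List of class `biopsy_result`: `predicted_lesion_id`,
#'   `hit_probability`, `hit`, `qualifying_labels`.
#' @export
simulate_biopsy <- function(predicted, annotation, isup_threshold,
                            needle_axis = NULL, hit_cutoff = 0.5,
                            needle_radius_px = 0L,
                            denominator = "predicted",
                            reference_fp = NULL) {
  stopifnot(inherits(predicted, "lesion"))
  if (is.null(annotation))
    stop("annotation is absent (non-RP patient): simulate_biopsy must not be called")
  stopifnot(inherits(annotation, "reference_annotation"))
  labelmap <- annotation$labelmap
  if (is.null(needle_axis)) needle_axis <- needle_axis(labelmap)

  qual <- as.integer(names(annotation$grades)[annotation$grades >= isup_threshold])
  pred_fp <- project_footprint(lesion_mask(predicted), needle_axis)
  if (needle_radius_px > 0) pred_fp$mask <- dilate_square(pred_fp$mask, needle_radius_px)

  if (is.null(reference_fp))
    reference_fp <- qualifying_footprint(annotation, isup_threshold, needle_axis)
  p <- hit_probability(pred_fp, reference_fp, denominator)  # 0 when no target qualifies
  structure(list(predicted_lesion_id = predicted$lesion_id,
                 hit_probability = p,
                 hit = p > hit_cutoff,
                 qualifying_labels = qual),
            class = "biopsy_result")
}

#' Footprint of the qualifying reference-lesion union
#'
#' Projects the union of all reference lesions with ISUP grade group at or
#' above the threshold; an empty union gives an empty footprint.
#'
#' @inheritParams simulate_biopsy
#' @return A `footprint2d`.
#' @export
qualifying_footprint <- function(annotation, isup_threshold, needle_axis = NULL) {
  labelmap <- annotation$labelmap
  if (is.null(needle_axis)) needle_axis <- needle_axis(labelmap)
  qual <- as.integer(names(annotation$grades)[annotation$grades >= isup_threshold])
  m <- if (length(qual)) labelmap$data %in% qual else rep(FALSE, length(labelmap$data))
  project_footprint(as_mask_grid(labelmap, array(m, dim(labelmap$data))), needle_axis)
}

# square (Chebyshev) dilation of a logical matrix by r pixels
dilate_square <- function(m, r) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (da in -r:r) for (db in -r:r) {
    if (da == 0 && db == 0) next
    src_r <- max(1, 1 - da):min(nr, nr - da)
    src_c <- max(1, 1 - db):min(nc, nc - db)
    out[src_r + da, src_c + db] <- out[src_r + da, src_c + db] | m[src_r, src_c]
  }
  out
}
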