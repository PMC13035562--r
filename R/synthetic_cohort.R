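#' Fit a log-normal distribution to a printed median and IQR
#'
#' `meanlog` is set from the median exactly; `sdlog` from the quartile ratio,
#' `log(q75/q25) / (2 * qnorm(0.75))`. Two parameters cannot match three
#' quantiles exactly when the printed quartiles are asymmetric around the
#' median, so the median is prioritised and the quartiles land within a few
#' percent of the printed values.
#'
#' @param median,q25,q75 Printed summary statistics (same units).
#' @return List with `meanlog`, `sdlog`.
#' @export
lognormal_from_quantiles <- function(median, q25, q75) {
  stopifnot(q25 > 0, q75 > q25, median > 0)
  list(meanlog = log(median),
       sdlog = log(q75 / q25) / (2 * stats::qnorm(0.75)))
}

#' Synthetic cohort configuration
#'
#' Describes the statistical structure of a simulated patient cohort:
#' prevalence of clinically significant prostate cancer (csPCa, ISUP grade
#' group >= 2), ISUP grade mix among positives, prostate and lesion volume
#' distributions, and grid geometry. Defaults follow the internal-cohort
#' composition the package models: csPCa prevalence 0.71, grade-group weights
#' 84:71:1:21 over ISUP {2,3,4,5}, prostate volume log-normal matched to
#' median 47 mL (IQR 36-74).
#'
#' Lesion volumes (log-normal, median 0.5 cc, truncated below
#' `min_lesion_volume_cc = 0.1`) and the lesion-multiplicity distribution
#' (1 lesion with probability 0.6, 2 with 0.4) are package choices: the
#' modeled study publishes no lesion-volume or multiplicity statistics.
#'
#' @param n_patients Cohort size.
#' @param prevalence_cspca csPCa prevalence in \[0, 1\].
#' @param grade_mix Named non-negative weights over ISUP grades 2..5 for the
#'   patient's highest grade; normalised internally.
#' @param prostate_volume List with `meanlog`, `sdlog` (cc) — see
#'   [lognormal_from_quantiles()].
#' @param lesions_per_positive Named weights over lesion counts for csPCa
#'   patients, e.g. `c("1" = 0.6, "2" = 0.4)`.
#' @param lesion_volume List with `meanlog`, `sdlog` for per-lesion volume (cc).
#' @param min_lesion_volume_cc Truncation floor for sampled csPCa lesion
#'   volumes; the default 0.1 keeps every generated csPCa lesion above the
#'   0.07 cc detectability cut.
#' @param grade1_negative_fraction Fraction of csPCa-negative patients that
#'   are RP patients with a single ISUP grade-group 1 lesion (rather than
#'   non-RP controls); default 0.
#' @param grid_shape,spacing_mm Voxel grid geometry (default 96^3 at 0.75 mm).
#' @param cohort Cohort tag stamped on generated patients.
#' @param seed Master seed; per-patient substreams are derived from it (see
#'   [patient_seed()]), so a cohort can be extended without reshuffling
#'   existing patients.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L,
                          prevalence_cspca = 0.71,
                          grade_mix = c("2" = 84, "3" = 71, "4" = 1, "5" = 21),
                          prostate_volume = lognormal_from_quantiles(47, 36, 74),
                          lesions_per_positive = c("1" = 0.6, "2" = 0.4),
                          lesion_volume = list(meanlog = log(0.5), sdlog = 0.7),
                          min_lesion_volume_cc = 0.1,
                          grade1_negative_fraction = 0,
                          grid_shape = c(96L, 96L, 96L),
                          spacing_mm = 0.75,
                          cohort = "internal",
                          seed = 1L) {
  grade_mix <- unlist(grade_mix)               # tolerate JSON-parsed lists
  lesions_per_positive <- unlist(lesions_per_positive)
  if (prevalence_cspca < 0 || prevalence_cspca > 1)
    stop("prevalence_cspca must be in [0, 1]")
  if (is.null(names(grade_mix)) || any(is.na(match(names(grade_mix), as.character(2:5)))))
    stop("grade_mix must be named with grades in 2..5")
  if (any(grade_mix < 0) || sum(grade_mix) <= 0) stop("grade_mix weights invalid")
  if (grade1_negative_fraction < 0 || grade1_negative_fraction > 1)
    stop("grade1_negative_fraction must be in [0, 1]")
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop("grid_shape must be 3 positive dimensions")
  structure(list(n_patients = as.integer(n_patients),
                 prevalence_cspca = prevalence_cspca,
                 grade_mix = grade_mix / sum(grade_mix),
                 prostate_volume = prostate_volume,
                 lesions_per_positive = lesions_per_positive / sum(lesions_per_positive),
                 lesion_volume = lesion_volume,
                 min_lesion_volume_cc = min_lesion_volume_cc,
                 grade1_negative_fraction = grade1_negative_fraction,
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = spacing_mm,
                 cohort = cohort,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Cohort presets
#'
#' `"internal"`: n = 250, prevalence 0.71, grade mix 84:71:1:21, prostate
#' volume median 47 (IQR 36-74). `"external"`: n = 77, prevalence 0.45,
#' grade mix 14:13:0:8, prostate volume median 52 (IQR 41-82).
#'
#' @param name `"internal"` or `"external"`.
#' @param ... Overrides passed to [cohort_config()].
#' @return A [cohort_config()].
#' @export
cohort_preset <- function(name = c("internal", "external"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    internal = list(n_patients = 250L, prevalence_cspca = 0.71,
                    grade_mix = c("2" = 84, "3" = 71, "4" = 1, "5" = 21),
                    prostate_volume = lognormal_from_quantiles(47, 36, 74),
                    cohort = "internal"),
    external = list(n_patients = 77L, prevalence_cspca = 0.45,
                    grade_mix = c("2" = 14, "3" = 13, "4" = 0, "5" = 8),
                    prostate_volume = lognormal_from_quantiles(52, 41, 82),
                    cohort = "external"))
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

#' Heatmap fidelity knobs
#'
#' Controls how faithfully the synthetic heatmap reproduces the reference
#' lesions, standing in for the error structure of a trained model. The
#' default is a perfect oracle: every csPCa lesion rendered in place at
#' `peak_probability`, no spurious lesions, no blur, no noise — so the
#' binarized heatmap equals the union of the csPCa lesion masks exactly.
#'
#' @param detection_probability Per-lesion probability that a csPCa lesion is
#'   rendered at all (1 = no dropout).
#' @param localization_offset_sd_mm SD (mm) of an isotropic Gaussian
#'   translation applied to each rendered lesion (0 = perfectly registered).
#' @param false_lesion_rate Expected number of spurious blobs per patient
#'   (Poisson).
#' @param false_lesion_volume Log-normal parameters for spurious-blob volume
#'   in cc (default median 0.2 cc, floored at 0.1 cc so false lesions survive
#'   the 0.07 cc filter and actually cost specificity).
#' @param blur_sd_mm Gaussian blur SD in mm applied to the rendered map.
#' @param background_noise_sd SD of additive Gaussian voxel noise.
#' @param peak_probability Heatmap value inside a rendered lesion (0, 1\].
#' @return List of class `heatmap_fidelity`.
#' @export
heatmap_fidelity <- function(detection_probability = 1,
                             localization_offset_sd_mm = 0,
                             false_lesion_rate = 0,
                             false_lesion_volume = list(meanlog = log(0.2), sdlog = 0.5),
                             blur_sd_mm = 0,
                             background_noise_sd = 0,
                             peak_probability = 0.95) {
  if (detection_probability < 0 || detection_probability > 1)
    stop("detection_probability must be in [0, 1]")
  if (localization_offset_sd_mm < 0 || false_lesion_rate < 0 ||
      blur_sd_mm < 0 || background_noise_sd < 0)
    stop("fidelity dispersions must be non-negative")
  if (peak_probability <= 0 || peak_probability > 1)
    stop("peak_probability must be in (0, 1]")
  structure(list(detection_probability = detection_probability,
                 localization_offset_sd_mm = localization_offset_sd_mm,
                 false_lesion_rate = false_lesion_rate,
                 false_lesion_volume = false_lesion_volume,
                 blur_sd_mm = blur_sd_mm,
                 background_noise_sd = background_noise_sd,
                 peak_probability = peak_probability),
            class = "heatmap_fidelity")
}

#' Per-patient RNG substream seed
#'
#' Stable documented rule: `(seed * 48271 + i * 65539) mod (2^31 - 1)`,
#' mapped away from 0. Extending a cohort re-derives the same seeds for
#' existing patient indices.
#'
#' @param seed Master seed (integer).
#' @param i Patient index (1-based).
#' @return Integer seed in 1 .. 2^31 - 2.
#' @export
patient_seed <- function(seed, i) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(i) * 65539
  as.integer(s %% m) + 1L
}

# axis-aligned ellipsoid mask via outer sums of per-axis squared offsets
ellipsoid_mask <- function(grid_shape, spacing_mm, center_vox, semi_mm) {
  q <- lapply(1:3, function(ax)
    ((seq_len(grid_shape[ax]) - center_vox[ax]) * spacing_mm[ax] / semi_mm[ax])^2)
  outer(outer(q[[1]], q[[2]], `+`), q[[3]], `+`) <= 1
}

# semi-axes (mm) for a target volume with fixed aspect ratios
semi_axes_for_volume <- function(volume_cc, ratios = c(1, 0.7, 0.85)) {
  s <- (3 * volume_cc * 1000 / (4 * pi * prod(ratios)))^(1 / 3)
  s * ratios
}

#' Sample an ellipsoidal prostate mask
#'
#' Draws a gland volume from the configured log-normal (unless `volume_cc`
#' is fixed) and rasterises an axis-aligned ellipsoid with anatomical aspect
#' ratios 1 : 0.7 : 0.85 (LR : AP : SI), centred in the grid. Draws whose
#' ellipsoid would not fit the grid (2-voxel margin) are redrawn up to 100
#' times; a fixed `volume_cc` that does not fit is an error.
#'
#' Uses the current RNG stream; seed externally for reproducibility.
#'
#' @param config A [cohort_config()].
#' @param volume_cc Optional fixed volume (cc).
#' @return A binary [voxel_grid()] with attributes `volume_cc_drawn` and
#'   `volume_cc_realized`.
#' @export
sample_prostate <- function(config, volume_cc = NULL) {
  shape <- config$grid_shape
  sp <- rep(config$spacing_mm, length.out = 3)
  extent <- shape * sp
  fits <- function(semi) all(2 * semi <= extent - 4 * sp)
  if (is.null(volume_cc)) {
    for (try in 1:100) {
      v <- stats::rlnorm(1, config$prostate_volume$meanlog, config$prostate_volume$sdlog)
      if (fits(semi_axes_for_volume(v))) { volume_cc <- v; break }
    }
    if (is.null(volume_cc)) stop("could not draw a prostate that fits the grid")
  } else if (!fits(semi_axes_for_volume(volume_cc))) {
    stop("prostate of ", volume_cc, " cc does not fit a ",
         paste(round(extent), collapse = "x"), " mm grid")
  }
  semi <- semi_axes_for_volume(volume_cc)
  center <- (shape + 1) / 2
  m <- ellipsoid_mask(shape, sp, center, semi)
  g <- voxel_grid(array(as.integer(m), shape), spacing_mm = sp, kind = "mask")
  attr(g, "volume_cc_drawn") <- volume_cc
  attr(g, "volume_cc_realized") <- voxels_to_cc(sum(m), g)
  g
}

# one ellipsoidal lesion at a random interior position; mildly anisotropic
place_lesion <- function(prostate, occupied, volume_cc, max_tries = 500L) {
  shape <- dim(prostate$data)
  sp <- prostate$spacing_mm
  inside <- which(prostate$data == 1L & !occupied)
  for (try in seq_len(max_tries)) {
    ratios <- stats::runif(3, 0.75, 1.25)
    ratios <- ratios / prod(ratios)^(1 / 3)
    semi <- semi_axes_for_volume(volume_cc, ratios)
    center <- arrayInd(inside[sample.int(length(inside), 1L)], shape)
    lo <- pmax(1L, floor(center - semi / sp - 1))
    hi <- pmin(shape, ceiling(center + semi / sp + 1))
    sub_shape <- hi - lo + 1L
    q <- lapply(1:3, function(ax)
      (((lo[ax]:hi[ax]) - center[ax]) * sp[ax] / semi[ax])^2)
    sub <- outer(outer(q[[1]], q[[2]], `+`), q[[3]], `+`) <= 1
    if (!any(sub)) next
    # full containment: the bounding box must not clip the ellipsoid
    if (any(center - semi / sp < 1) || any(center + semi / sp > shape)) next
    idx <- which(sub)
    co <- arrayInd(idx, sub_shape)
    lin <- (lo[1] - 1L + co[, 1]) +
           (lo[2] - 2L + co[, 2]) * shape[1] +
           (lo[3] - 2L + co[, 3]) * shape[1] * shape[2]
    if (all(prostate$data[lin] == 1L) && !any(occupied[lin]))
      return(lin)
  }
  stop("could not place a ", format(volume_cc), " cc lesion after ",
       max_tries, " tries")
}

#' Sample graded reference lesions inside a prostate
#'
#' Places `n_lesions` non-overlapping ellipsoidal lesions fully inside the
#' prostate mask, labelled 1..n in placement order, each with its assigned
#' ISUP grade group. Uses the current RNG stream.
#'
#' Requested volumes are capped at 15% of the realized gland volume (a tumor
#' larger than that cannot reliably sit fully inside an ellipsoidal gland's
#' short axis); if a lesion still cannot be placed within the retry budget it
#' is shrunk by 20% steps (at most 3 times, never below the request's floor)
#' before placement is abandoned with an error.
#'
#' @param prostate Binary prostate [voxel_grid()].
#' @param n_lesions Number of lesions.
#' @param grades Integer vector of length `n_lesions` (ISUP 1..5).
#' @param volumes_cc Lesion volumes in cc (length `n_lesions`).
#' @return A [reference_annotation()] (with `prostate_mask` attached).
#' @export
sample_reference_lesions <- function(prostate, n_lesions, grades, volumes_cc) {
  stopifnot(length(grades) == n_lesions, length(volumes_cc) == n_lesions)
  shape <- dim(prostate$data)
  gland_cc <- voxels_to_cc(sum(prostate$data), prostate)
  volumes_cc <- pmin(volumes_cc, 0.15 * gland_cc)
  labels <- array(0L, shape)
  occupied <- array(FALSE, shape)
  for (j in seq_len(n_lesions)) {
    lin <- NULL
    v <- volumes_cc[j]
    for (shrink in 0:3) {
      lin <- tryCatch(place_lesion(prostate, occupied, v * 0.8^shrink),
                      error = function(e) NULL)
      if (!is.null(lin)) break
    }
    if (is.null(lin))
      stop("could not place a ", format(v), " cc lesion in a ",
           format(gland_cc), " cc gland")
    labels[lin] <- j
    occupied[lin] <- TRUE
  }
  labelmap <- voxel_grid(labels, spacing_mm = prostate$spacing_mm, kind = "labelmap")
  grades_named <- stats::setNames(as.integer(grades), as.character(seq_len(n_lesions)))
  reference_annotation(labelmap, grades_named, prostate_mask = prostate, check = FALSE)
}

# random interior voxel offsets for a Gaussian localization error (in voxels)
draw_offset_vox <- function(sd_mm, spacing_mm) {
  if (sd_mm <= 0) return(c(0L, 0L, 0L))
  as.integer(round(stats::rnorm(3, 0, sd_mm) / spacing_mm))
}

shift_indices <- function(idx, offset, shape) {
  if (all(offset == 0L)) return(idx)
  co <- sweep(arrayInd(idx, shape), 2L, offset, `+`)
  keep <- co[, 1] >= 1 & co[, 1] <= shape[1] &
          co[, 2] >= 1 & co[, 2] <= shape[2] &
          co[, 3] >= 1 & co[, 3] <= shape[3]
  co <- co[keep, , drop = FALSE]
  co[, 1] + (co[, 2] - 1L) * shape[1] + (co[, 3] - 1L) * shape[1] * shape[2]
}

#' Render a synthetic heatmap from a reference annotation
#'
#' Each reference lesion of ISUP grade group >= 2 is rendered independently
#' with probability `detection_probability` at value `peak_probability`,
#' optionally translated by a Gaussian localization error. Grade-1 lesions
#' are never rendered (the heatmap models a csPCa detector). Spurious blobs
#' (count ~ Poisson(`false_lesion_rate`)) are placed inside the prostate.
#' Gaussian blur and background noise are then applied and values clipped to
#' \[0, 1\]. Uses the current RNG stream.
#'
#' @param annotation A [reference_annotation()], or `NULL` for a patient
#'   with no reference lesions.
#' @param fidelity A [heatmap_fidelity()].
#' @param prostate Binary prostate mask grid; required when `annotation` is
#'   `NULL` or lacks one and `false_lesion_rate > 0`.
#' @param grid_shape,spacing_mm Grid geometry when `annotation` is `NULL`.
#' @return A `"heatmap"` [voxel_grid()].
#' @export
render_heatmap <- function(annotation, fidelity = heatmap_fidelity(),
                           prostate = NULL, grid_shape = NULL, spacing_mm = 0.75) {
  if (is.null(prostate) && !is.null(annotation)) prostate <- annotation$prostate_mask
  if (!is.null(annotation)) {
    shape <- dim(annotation$labelmap$data)
    sp <- annotation$labelmap$spacing_mm
  } else if (!is.null(prostate)) {
    shape <- dim(prostate$data)
    sp <- prostate$spacing_mm
  } else {
    if (is.null(grid_shape)) stop("need an annotation, prostate mask or grid_shape")
    shape <- grid_shape
    sp <- rep(spacing_mm, length.out = 3)
  }
  heat <- array(0, shape)

  if (!is.null(annotation)) {
    for (lb in names(annotation$grades)) {
      if (annotation$grades[[lb]] < 2L) next      # isPCa: not a csPCa target
      rendered <- stats::runif(1) < fidelity$detection_probability
      off <- draw_offset_vox(fidelity$localization_offset_sd_mm, sp[1])
      if (!rendered) next
      idx <- which(annotation$labelmap$data == as.integer(lb))
      idx <- shift_indices(idx, off, shape)
      heat[idx] <- pmax(heat[idx], fidelity$peak_probability)
    }
  }

  if (fidelity$false_lesion_rate > 0) {
    if (is.null(prostate))
      stop("false_lesion_rate > 0 needs a prostate mask to place blobs in")
    n_false <- stats::rpois(1, fidelity$false_lesion_rate)
    inside <- which(prostate$data == 1L)
    for (f in seq_len(n_false)) {
      v <- max(stats::rlnorm(1, fidelity$false_lesion_volume$meanlog,
                             fidelity$false_lesion_volume$sdlog), 0.1)
      semi <- semi_axes_for_volume(v)
      center <- arrayInd(inside[sample.int(length(inside), 1L)], shape)
      m <- ellipsoid_mask(shape, sp, center, semi)
      heat[m] <- pmax(heat[m], fidelity$peak_probability)
    }
  }

  if (fidelity$blur_sd_mm > 0)
    heat <- array(gauss_blur_3d(as.numeric(heat), shape, fidelity$blur_sd_mm / sp),
                  shape)
  if (fidelity$background_noise_sd > 0) {
    heat <- heat + stats::rnorm(length(heat), 0, fidelity$background_noise_sd)
    heat <- pmin(pmax(heat, 0), 1)
  }
  # rendered values are already in [0, 1]; skip revalidation of the big array
  structure(list(data = heat, spacing_mm = sp, kind = "heatmap",
                 axes = c("LR", "AP", "SI")), class = "voxel_grid")
}

# truncated log-normal draw (simple resampling, floor fallback)
rlnorm_trunc <- function(n, meanlog, sdlog, lower) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (t in 1:50) {
    bad <- x < lower
    if (!any(bad)) break
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  pmax(x, lower)
}

#' Build one synthetic patient
#'
#' Seeds the RNG with [patient_seed()] and draws, in a fixed order: disease
#' status, highest ISUP grade, lesion count, lesion volumes, prostate volume,
#' lesion placements, heatmap rendering. The patient's highest grade is drawn
#' from `grade_mix`; any second lesion's grade is uniform on 2..max so the
#' per-patient maximum matches the drawn grade.
#'
#' @param config A [cohort_config()].
#' @param fidelity A [heatmap_fidelity()].
#' @param i Patient index (1-based).
#' @return List with `patient_id`, `arm`, `cohort`, `heatmap`, `annotation`
#'   (`NULL` for non-RP), `prostate`, `seed`.
#' @export
build_patient <- function(config, fidelity = heatmap_fidelity(), i = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(patient_seed(config$seed, i))

  positive <- stats::runif(1) < config$prevalence_cspca
  isup1 <- !positive && stats::runif(1) < config$grade1_negative_fraction
  arm <- if (positive || isup1) "RP" else "non-RP"

  if (positive) {
    gmax <- as.integer(sample(names(config$grade_mix), 1L,
                              prob = config$grade_mix))
    n_lesions <- as.integer(sample(names(config$lesions_per_positive), 1L,
                                   prob = config$lesions_per_positive))
    grades <- c(gmax, if (n_lesions > 1L)
      (2:gmax)[sample.int(gmax - 1L, n_lesions - 1L, replace = TRUE)])
    volumes <- rlnorm_trunc(n_lesions, config$lesion_volume$meanlog,
                            config$lesion_volume$sdlog,
                            config$min_lesion_volume_cc)
  } else if (isup1) {
    grades <- 1L
    n_lesions <- 1L
    volumes <- rlnorm_trunc(1L, config$lesion_volume$meanlog,
                            config$lesion_volume$sdlog,
                            config$min_lesion_volume_cc)
  } else {
    grades <- integer(0)
    n_lesions <- 0L
    volumes <- numeric(0)
  }

  prostate <- sample_prostate(config)
  annotation <- if (arm == "RP")
    sample_reference_lesions(prostate, n_lesions, grades, volumes) else NULL
  heatmap <- render_heatmap(annotation, fidelity, prostate = prostate)

  list(patient_id = sprintf("P%04d", i), arm = arm, cohort = config$cohort,
       heatmap = heatmap, annotation = annotation, prostate = prostate,
       seed = patient_seed(config$seed, i))
}

#' Tabulate the per-patient sampling plan of a cohort
#'
#' Re-derives, from the per-patient substreams, the scalar draws that
#' [build_patient()] would make (arm, highest grade, lesion count) without
#' rasterising any volume. Cheap way to inspect or test cohort composition.
#'
#' @param config A [cohort_config()].
#' @return data.frame with one row per patient: `patient_id`, `arm`,
#'   `max_grade` (0 for non-RP), `n_lesions`.
#' @export
cohort_plan <- function(config) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  rows <- lapply(seq_len(config$n_patients), function(i) {
    set.seed(patient_seed(config$seed, i))
    positive <- stats::runif(1) < config$prevalence_cspca
    isup1 <- !positive && stats::runif(1) < config$grade1_negative_fraction
    if (positive) {
      gmax <- as.integer(sample(names(config$grade_mix), 1L, prob = config$grade_mix))
      n_lesions <- as.integer(sample(names(config$lesions_per_positive), 1L,
                                     prob = config$lesions_per_positive))
    } else if (isup1) {
      gmax <- 1L; n_lesions <- 1L
    } else {
      gmax <- 0L; n_lesions <- 0L
    }
    data.frame(patient_id = sprintf("P%04d", i),
               arm = if (positive || isup1) "RP" else "non-RP",
               max_grade = gmax, n_lesions = n_lesions,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic cohort on disk
#'
#' Builds every patient with [build_patient()] and writes, under `out_dir`:
#' one heatmap NIfTI per patient, a labelmap NIfTI plus JSON grade sidecar
#' per RP patient, `manifest.csv` in the [read_manifest()] dialect, and
#' `provenance.json` (config, fidelity, seed, package version). Fully
#' reproducible: the same config and fidelity give byte-identical files.
#'
#' @param config A [cohort_config()].
#' @param fidelity A [heatmap_fidelity()].
#' @param out_dir Output directory (created if missing).
#' @return Path to `manifest.csv`, invisibly.
#' @export
generate_cohort <- function(config, fidelity = heatmap_fidelity(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    p <- build_patient(config, fidelity, i)
    hm <- sprintf("%s_heatmap.nii.gz", p$patient_id)
    write_volume(p$heatmap, file.path(out_dir, hm))
    ann <- gr <- NA_character_
    if (!is.null(p$annotation)) {
      ann <- sprintf("%s_labels.nii.gz", p$patient_id)
      gr <- sprintf("%s_grades.json", p$patient_id)
      write_volume(p$annotation$labelmap, file.path(out_dir, ann))
      jsonlite::write_json(as.list(p$annotation$grades),
                           file.path(out_dir, gr), auto_unbox = TRUE)
    }
    rows[[i]] <- data.frame(patient_id = p$patient_id, arm = p$arm,
                            cohort = p$cohort, heatmap_path = hm,
                            annotation_path = ann, grades_path = gr,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  write_manifest(manifest, manifest_path)
  jsonlite::write_json(
    list(generator = "biopsim", version = as.character(utils::packageVersion("biopsim")),
         config = unclass(config), fidelity = unclass(fidelity)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
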