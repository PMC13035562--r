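#' Cohort manifests and reference annotations
#'
#' A manifest lists one patient per row with columns `patient_id`, `arm`
#' (`"RP"` for prostatectomy patients with a histopathology reference
#' standard, `"non-RP"` for biopsy-/MRI-negative controls), `cohort`
#' (`"internal"` or `"external"`), `heatmap_path`, `annotation_path` and
#' `grades_path`. Paths are resolved relative to the manifest's directory.
#' RP patients must have an annotation and grade sidecar; non-RP patients
#' must not (they carry no reference lesions by design).
#'
#' CSV (header row, UTF-8) and JSON (array of records) dialects are accepted.
#'
#' @param path Manifest file (`.csv` or `.json`).
#' @return A data.frame of class `patient_manifest`, one row per patient, in
#'   file order, with attribute `base_dir` used to resolve relative paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  validate_manifest(df, base_dir = dirname(path))
}

validate_manifest <- function(df, base_dir = ".") {
  required <- c("patient_id", "arm", "cohort", "heatmap_path")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("annotation_path", "grades_path"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  df$patient_id <- as.character(df$patient_id)

  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup)) stop("duplicate patient_id in manifest: ",
                        paste(unique(dup), collapse = ", "))
  bad_arm <- setdiff(unique(df$arm), c("RP", "non-RP"))
  if (length(bad_arm)) stop("invalid arm value(s): ", paste(bad_arm, collapse = ", "))
  bad_cohort <- setdiff(unique(df$cohort), c("internal", "external"))
  if (length(bad_cohort)) stop("invalid cohort tag(s): ", paste(bad_cohort, collapse = ", "))

  has_ann <- !is.na(df$annotation_path) & nzchar(df$annotation_path)
  has_gr <- !is.na(df$grades_path) & nzchar(df$grades_path)
  rp <- df$arm == "RP"
  if (any(rp & !(has_ann & has_gr)))
    stop("RP patient(s) without annotation/grades: ",
         paste(df$patient_id[rp & !(has_ann & has_gr)], collapse = ", "))
  if (any(!rp & (has_ann | has_gr)))
    stop("non-RP patient(s) with an annotation: ",
         paste(df$patient_id[!rp & (has_ann | has_gr)], collapse = ", "))

  structure(df, base_dir = base_dir, class = c("patient_manifest", "data.frame"))
}

#' Write a manifest to CSV
#' @param manifest A `patient_manifest` (or compatible data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

resolve_manifest_path <- function(manifest, p) {
  base <- attr(manifest, "base_dir")
  ifelse(is.na(p) | !nzchar(p), NA_character_,
         ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p)))
}

#' Read a per-lesion grade sidecar
#'
#' The sidecar is a JSON object mapping labelmap label (as a string key) to
#' the lesion's ISUP grade group in 1..5, e.g. `{"1": 3, "2": 2}`. NIfTI has
#' no standard per-label metadata, hence the external file.
#'
#' @param path JSON file path.
#' @return Named integer vector, names = labels.
#' @export
read_grades <- function(path) {
  if (!file.exists(path)) stop("grade sidecar not found: ", path)
  x <- jsonlite::fromJSON(path)
  if (length(x) == 0) return(stats::setNames(integer(0), character(0)))
  g <- vapply(x, function(v) as.numeric(v[[1]]), numeric(1))
  if (any(g != round(g)) || any(g < 1) || any(g > 5))
    stop("ISUP grade group must be an integer in 1..5; got: ",
         paste(g[g < 1 | g > 5 | g != round(g)], collapse = ", "))
  stats::setNames(as.integer(g), names(x))
}

#' Reference annotation: graded lesion labelmap
#'
#' Bundles a lesion labelmap with its per-lesion ISUP grade groups (and an
#' optional prostate mask). Every nonzero label must have exactly one grade
#' entry and vice versa, and each label must form a single connected
#' component under the stated connectivity.
#'
#' @param labelmap A `"labelmap"` [voxel_grid()].
#' @param grades Named integer vector mapping label -> ISUP grade group (1-5).
#' @param prostate_mask Optional binary `voxel_grid` on the same grid.
#' @param connectivity 3D connectivity (6, 18 or 26) used for the
#'   connectedness check.
#' @param check If `TRUE` (default) verify the label-connectedness invariant.
#' @return An object of class `reference_annotation`.
#' @export
reference_annotation <- function(labelmap, grades, prostate_mask = NULL,
                                 connectivity = 26, check = TRUE) {
  stopifnot(inherits(labelmap, "voxel_grid"), labelmap$kind == "labelmap")
  labels <- sort(unique(as.integer(labelmap$data)))
  labels <- labels[labels > 0]
  have <- sort(as.integer(names(grades)))
  if (!identical(labels, have))
    stop("labelmap labels {", paste(labels, collapse = ","),
         "} and grade entries {", paste(have, collapse = ","), "} must match")
  if (length(grades) && (any(grades < 1L) || any(grades > 5L)))
    stop("grades must be in 1..5")
  if (!is.null(prostate_mask)) stopifnot_same_grid(labelmap, prostate_mask)
  if (check && length(labels)) {
    for (lb in labels) {
      m <- labelmap$data == lb
      lab <- cc_label_3d(as.logical(m), dim(labelmap$data), as.integer(connectivity))
      if (attr(lab, "n_components") != 1L)
        stop("label ", lb, " is not a single connected component (connectivity ",
             connectivity, ")")
    }
  }
  structure(list(labelmap = labelmap, grades = grades,
                 prostate_mask = prostate_mask, connectivity = connectivity),
            class = "reference_annotation")
}

#' Highest ISUP grade group in an annotation
#' @param annotation A `reference_annotation`, or `NULL` for a patient
#'   without a histopathology reference (treated as grade 0).
#' @return Integer; 0 when there are no lesions.
#' @export
max_isup_grade <- function(annotation) {
  if (is.null(annotation) || length(annotation$grades) == 0L) return(0L)
  max(annotation$grades)
}

#' @export
print.reference_annotation <- function(x, ...) {
  cat(sprintf("<reference_annotation> %d lesion(s); grades: %s\n",
              length(x$grades),
              if (length(x$grades)) paste(sprintf("%s=ISUP%d", names(x$grades), x$grades),
                                          collapse = ", ") else "none"))
  invisible(x)
}

#' Load the annotation referenced by one manifest row
#' @param manifest A `patient_manifest`.
#' @param patient_id Patient to load.
#' @return A `reference_annotation`, or `NULL` for non-RP patients.
#' @export
load_annotation <- function(manifest, patient_id) {
  row <- manifest[manifest$patient_id == patient_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("patient not found in manifest: ", patient_id)
  if (row$arm != "RP") return(NULL)
  labelmap <- read_volume(resolve_manifest_path(manifest, row$annotation_path),
                          kind = "labelmap")
  grades <- read_grades(resolve_manifest_path(manifest, row$grades_path))
  reference_annotation(labelmap, grades, check = FALSE)
}
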