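#' Classify one patient at an ISUP threshold
#'
#' Applies the patient-level decision rules of the simulated-biopsy analysis:
#'
#' * Disease-positive patients (RP patients whose highest lesion grade is at
#'   or above the threshold) are **TP** if any simulated biopsy hits
#'   (hit probability strictly above the cut-off) and **FN** otherwise —
#'   including patients where the model found a lesion but every biopsy
#'   missed.
#' * Disease-negative patients (non-RP patients, who carry no csPCa by
#'   construction, and RP patients whose highest grade is below the
#'   threshold) are **FP** if the model detected *any* lesion surviving
#'   extraction — no biopsy-hit requirement — and **TN** otherwise.
#' * RP patients whose prostatectomy showed only ISUP grade group 1 sit in
#'   neither the positive nor the negative group of the standard analysis;
#'   by default they are `excluded` at both thresholds
#'   (`isup1_policy = "exclude"`), or counted as negatives with
#'   `isup1_policy = "count_negative"`.
#'
#' @param patient_id Patient identifier.
#' @param arm `"RP"` or `"non-RP"`.
#' @param predicted List of `lesion` objects that survived extraction,
#'   filtering and top-k selection (may be empty).
#' @param annotation A [reference_annotation()] for RP patients, `NULL` for
#'   non-RP patients.
#' @param isup_threshold 2 or 3.
#' @param isup1_policy `"exclude"` (default) or `"count_negative"`.
#' @param needle_axis,hit_cutoff,needle_radius_px,denominator Passed to
#'   [simulate_biopsy()].
#' @param cohort Cohort tag carried through to the call table.
#' @return One-row data.frame of class `patient_call` with columns
#'   `patient_id`, `cohort`, `isup_threshold`, `disease_positive`,
#'   `model_detected`, `biopsy_hit`, `n_biopsies`, `max_hit_probability`,
#'   `call` (one of TP/FP/TN/FN/excluded).
#' @export
classify_patient <- function(patient_id, arm, predicted, annotation,
                             isup_threshold,
                             isup1_policy = c("exclude", "count_negative"),
                             needle_axis = NULL, hit_cutoff = 0.5,
                             needle_radius_px = 0L, denominator = "predicted",
                             cohort = NA_character_) {
  isup1_policy <- match.arg(isup1_policy)
  if (!arm %in% c("RP", "non-RP")) stop("arm must be 'RP' or 'non-RP'")
  if (arm == "RP" && is.null(annotation))
    stop("RP patient ", patient_id, " has no reference annotation")

  model_detected <- length(predicted) > 0L
  max_grade <- if (arm == "RP") max_isup_grade(annotation) else 0L
  excluded <- arm == "RP" && max_grade == 1L && isup1_policy == "exclude"
  disease_positive <- arm == "RP" && max_grade >= isup_threshold

  biopsy_hit <- FALSE
  max_p <- NA_real_
  n_biopsies <- 0L
  if (arm == "RP" && model_detected) {
    ref_fp <- qualifying_footprint(annotation, isup_threshold, needle_axis)
    results <- lapply(predicted, simulate_biopsy, annotation = annotation,
                      isup_threshold = isup_threshold,
                      needle_axis = needle_axis, hit_cutoff = hit_cutoff,
                      needle_radius_px = needle_radius_px,
                      denominator = denominator, reference_fp = ref_fp)
    probs <- vapply(results, `[[`, numeric(1), "hit_probability")
    biopsy_hit <- any(vapply(results, `[[`, logical(1), "hit"))
    max_p <- max(probs)
    n_biopsies <- length(results)
  }

  call <- if (excluded) "excluded"
          else if (disease_positive && biopsy_hit) "TP"
          else if (disease_positive) "FN"
          else if (model_detected) "FP"
          else "TN"

  structure(data.frame(patient_id = patient_id, cohort = cohort,
                       isup_threshold = as.integer(isup_threshold),
                       disease_positive = disease_positive,
                       model_detected = model_detected,
                       biopsy_hit = biopsy_hit,
                       n_biopsies = n_biopsies,
                       max_hit_probability = max_p,
                       call = call,
                       stringsAsFactors = FALSE),
            class = c("patient_call", "data.frame"))
}

#' Classify a whole cohort at one or more ISUP thresholds
#'
#' @param records A `patient_manifest` or data.frame with columns
#'   `patient_id`, `arm` and (optionally) `cohort`.
#' @param predictions Named list (by patient_id) of selected-lesion lists.
#' @param annotations Named list (by patient_id) of
#'   [reference_annotation()]s; entries for non-RP patients may be absent or
#'   `NULL`.
#' @param thresholds ISUP thresholds to evaluate (default `c(2, 3)`).
#' @param ... Passed to [classify_patient()].
#' @return data.frame with one row per patient per threshold, in manifest
#'   order.
#' @export
classify_cohort <- function(records, predictions, annotations,
                            thresholds = c(2L, 3L), ...) {
  if (anyDuplicated(records$patient_id))
    stop("duplicate patient ids in records")
  if (!"cohort" %in% names(records)) records$cohort <- NA_character_
  rows <- list()
  for (thr in thresholds) {
    for (r in seq_len(nrow(records))) {
      pid <- records$patient_id[r]
      rows[[length(rows) + 1L]] <- classify_patient(
        patient_id = pid, arm = records$arm[r],
        predicted = predictions[[pid]],
        annotation = annotations[[pid]],
        isup_threshold = thr, cohort = records$cohort[r], ...)
    }
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  calls
}
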