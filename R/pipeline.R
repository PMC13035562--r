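#' Run configuration
#'
#' One place for every procedure constant of the simulated-biopsy analysis.
#' The defaults reproduce the standard procedure: candidate lesions at
#' heatmap threshold 0.5, volume filter 0.07 cc, two biopsied lesions, point
#' needle along the cranio-caudal axis, biopsy positive when the hit
#' probability strictly exceeds 0.5, evaluation at ISUP >= 2 and >= 3, Wilson
#' 95% confidence intervals, ISUP-1 prostatectomy patients excluded.
#'
#' @param extraction An [extraction_config()].
#' @param needle_axis Needle axis (default `NULL` = the grid's `"SI"` axis).
#' @param hit_cutoff Biopsy positivity cut-off (strict), default 0.5.
#' @param thresholds ISUP thresholds, subset of `c(2, 3)`.
#' @param ci_method,ci_level Interval settings for reporting.
#' @param isup1_policy `"exclude"` or `"count_negative"`.
#' @param denominator Overlap statistic for [hit_probability()].
#' @param seed Seed recorded in provenance (generation uses the cohort
#'   config's own seed).
#' @return List of class `run_config`.
#' @export
run_config <- function(extraction = extraction_config(), needle_axis = NULL,
                       hit_cutoff = 0.5, thresholds = c(2L, 3L),
                       ci_method = "wilson", ci_level = 0.95,
                       isup1_policy = "exclude", denominator = "predicted",
                       seed = 1L) {
  if (!all(thresholds %in% c(2L, 3L))) stop("thresholds must be a subset of {2, 3}")
  if (hit_cutoff < 0 || hit_cutoff >= 1) stop("hit_cutoff must be in [0, 1)")
  structure(list(extraction = extraction, needle_axis = needle_axis,
                 hit_cutoff = hit_cutoff, thresholds = as.integer(thresholds),
                 ci_method = ci_method, ci_level = ci_level,
                 isup1_policy = isup1_policy, denominator = denominator,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_provenance <- function(out_dir, what, config) {
  jsonlite::write_json(
    list(stage = what, package = "biopsim",
         version = as.character(utils::packageVersion("biopsim")),
         r_version = as.character(getRversion()),
         config = rapply(unclass(config), unclass, how = "replace")),
    file.path(out_dir, paste0(what, "_provenance.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
}

#' Generate a synthetic cohort (pipeline stage)
#'
#' Thin wrapper over [generate_cohort()] that accepts a JSON config document
#' and records provenance. The JSON document may contain `cohort_config`
#' (fields of [cohort_config()], or a string preset name under `preset`) and
#' `fidelity` (fields of [heatmap_fidelity()]).
#'
#' @param config A [cohort_config()], or the path to a JSON config document.
#' @param out_dir Output directory.
#' @param fidelity A [heatmap_fidelity()] (ignored when the JSON document
#'   provides one).
#' @return Manifest path, invisibly.
#' @export
cmd_generate <- function(config, out_dir, fidelity = heatmap_fidelity()) {
  if (is.character(config)) {
    doc <- jsonlite::fromJSON(config)
    cc <- as.list(doc$cohort_config)
    preset <- cc$preset
    cc$preset <- NULL
    config <- if (!is.null(preset)) do.call(cohort_preset, c(list(name = preset), cc))
              else do.call(cohort_config, cc)
    if (!is.null(doc$fidelity))
      fidelity <- do.call(heatmap_fidelity, as.list(doc$fidelity))
  }
  stopifnot(inherits(config, "cohort_config"), inherits(fidelity, "heatmap_fidelity"))
  manifest <- generate_cohort(config, fidelity, out_dir)
  invisible(manifest)
}

#' Simulate biopsies for every patient in a manifest (pipeline stage)
#'
#' For each patient: read the heatmap, extract-filter-select predicted
#' lesions, simulate one biopsy per selected lesion against the reference
#' annotation, and classify the patient at each ISUP threshold. Emits
#' `lesions.csv` (predicted-lesion table), `biopsies.csv` (per-biopsy hit
#' probabilities) and `calls.csv` (per-patient calls), plus provenance.
#'
#' @param manifest_path Path to a manifest (see [read_manifest()]).
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The call table, invisibly.
#' @export
cmd_simulate <- function(manifest_path, config = run_config(), out_dir) {
  manifest <- read_manifest(manifest_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  lesion_rows <- list(); biopsy_rows <- list(); call_rows <- list()
  for (r in seq_len(nrow(manifest))) {
    pid <- manifest$patient_id[r]
    heatmap <- read_volume(resolve_manifest_path(manifest, manifest$heatmap_path[r]),
                           kind = "heatmap")
    annotation <- load_annotation(manifest, pid)
    predicted <- extract_lesions(heatmap, config$extraction)
    lesion_rows[[pid]] <- lesion_table(predicted, pid)

    for (thr in config$thresholds) {
      if (manifest$arm[r] == "RP" && length(predicted)) {
        for (les in predicted) {
          b <- simulate_biopsy(les, annotation, thr,
                               needle_axis = config$needle_axis,
                               hit_cutoff = config$hit_cutoff,
                               denominator = config$denominator)
          biopsy_rows[[length(biopsy_rows) + 1L]] <- data.frame(
            patient_id = pid, predicted_lesion_id = b$predicted_lesion_id,
            isup_threshold = thr, hit_probability = b$hit_probability,
            hit = b$hit, stringsAsFactors = FALSE)
        }
      }
      call_rows[[length(call_rows) + 1L]] <- classify_patient(
        pid, manifest$arm[r], predicted, annotation, thr,
        isup1_policy = config$isup1_policy, needle_axis = config$needle_axis,
        hit_cutoff = config$hit_cutoff, denominator = config$denominator,
        cohort = manifest$cohort[r])
    }
  }
  lesions <- do.call(rbind, c(lesion_rows, list(make.row.names = FALSE)))
  biopsies <- if (length(biopsy_rows))
    do.call(rbind, c(biopsy_rows, list(make.row.names = FALSE)))
  else data.frame(patient_id = character(0), predicted_lesion_id = integer(0),
                  isup_threshold = integer(0), hit_probability = numeric(0),
                  hit = logical(0))
  calls <- do.call(rbind, c(call_rows, list(make.row.names = FALSE)))

  utils::write.csv(lesions, file.path(out_dir, "lesions.csv"), row.names = FALSE)
  utils::write.csv(biopsies, file.path(out_dir, "biopsies.csv"), row.names = FALSE)
  utils::write.csv(calls, file.path(out_dir, "calls.csv"), row.names = FALSE)
  write_provenance(out_dir, "simulate", config)
  invisible(calls)
}

#' Evaluate call tables into a diagnostic report (pipeline stage)
#'
#' @param calls Path to a `calls.csv` from [cmd_simulate()], or the call
#'   table itself.
#' @param config A [run_config()] (CI method and level).
#' @param out_dir Output directory for `report.csv` / `report.json` /
#'   `report.txt`.
#' @return The [cohort_report()], invisibly.
#' @export
cmd_evaluate <- function(calls, config = run_config(), out_dir) {
  if (is.character(calls)) calls <- utils::read.csv(calls, stringsAsFactors = FALSE)
  if (!nrow(calls)) stop("empty call table")
  report <- cohort_report(calls, thresholds = config$thresholds,
                          ci_method = config$ci_method, level = config$ci_level)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(report, out_dir)
  write_provenance(out_dir, "evaluate", config)
  invisible(report)
}

#' Simulate a synthetic cohort fully in memory
#'
#' Runs `build -> extract -> biopsy -> classify` per patient without touching
#' disk. Used for property checks and calibration experiments where the
#' volumes themselves are not needed afterwards.
#'
#' @param cohort A [cohort_config()].
#' @param fidelity A [heatmap_fidelity()].
#' @param config A [run_config()].
#' @return Call table (one row per patient per threshold).
#' @export
simulate_synthetic_cohort <- function(cohort, fidelity = heatmap_fidelity(),
                                      config = run_config()) {
  call_rows <- list()
  for (i in seq_len(cohort$n_patients)) {
    p <- build_patient(cohort, fidelity, i)
    predicted <- extract_lesions(p$heatmap, config$extraction)
    for (thr in config$thresholds) {
      call_rows[[length(call_rows) + 1L]] <- classify_patient(
        p$patient_id, p$arm, predicted, p$annotation, thr,
        isup1_policy = config$isup1_policy, needle_axis = config$needle_axis,
        hit_cutoff = config$hit_cutoff, denominator = config$denominator,
        cohort = p$cohort)
    }
  }
  calls <- do.call(rbind, c(call_rows, list(make.row.names = FALSE)))
  rownames(calls) <- NULL
  calls
}
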