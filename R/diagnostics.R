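#' Confusion matrix from patient calls
#'
#' Tallies TP/FP/TN/FN over a call table at a single ISUP threshold;
#' `excluded` calls are dropped from all counts.
#'
#' @param calls data.frame of patient calls (see [classify_patient()]).
#' @param threshold The ISUP threshold the calls must share.
#' @return List of class `confusion_matrix` with integer fields `tp`, `fp`,
#'   `tn`, `fn`, plus `isup_threshold`, `cohort`, `n_excluded`.
#' @export
confusion_from_calls <- function(calls, threshold) {
  if (nrow(calls) && !all(calls$isup_threshold == threshold))
    stop("calls mix ISUP thresholds; filter to threshold ", threshold, " first")
  tab <- table(factor(calls$call, levels = c("TP", "FP", "TN", "FN", "excluded")))
  structure(list(tp = unname(tab[["TP"]]), fp = unname(tab[["FP"]]),
                 tn = unname(tab[["TN"]]), fn = unname(tab[["FN"]]),
                 n_excluded = unname(tab[["excluded"]]),
                 isup_threshold = as.integer(threshold),
                 cohort = if (nrow(calls)) unique(stats::na.omit(calls$cohort))[1] else NA_character_),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> ISUP >= %d: TP %d, FN %d, TN %d, FP %d (excluded %d)\n",
              x$isup_threshold, x$tp, x$fn, x$tn, x$fp, x$n_excluded))
  invisible(x)
}

#' Binomial proportion with confidence interval
#'
#' Point estimate `successes / n` with a two-sided confidence interval by the
#' Wilson score method (default), exact Clopper-Pearson (beta quantiles), or
#' the Wald normal approximation clipped to \[0, 1\].
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param method `"wilson"`, `"clopper-pearson"` or `"wald"`.
#' @param level Confidence level, default 0.95.
#' @param name Optional metric name stamped on the row.
#' @return One-row data.frame: `name`, `estimate`, `ci_low`, `ci_high`,
#'   `successes`, `n`, `ci_method`, `level`.
#' @export
proportion_with_ci <- function(successes, n,
                               method = c("wilson", "clopper-pearson", "wald"),
                               level = 0.95, name = NA_character_) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1")
  if (successes < 0 || successes > n) stop("successes must be in 0..n")
  p <- successes / n
  alpha <- 1 - level
  z <- stats::qnorm(1 - alpha / 2)
  ci <- switch(method,
    wilson = {
      denom <- 1 + z^2 / n
      center <- (p + z^2 / (2 * n)) / denom
      half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
      c(center - half, center + half)
    },
    `clopper-pearson` = c(
      if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, n - successes + 1),
      if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1, n - successes)),
    wald = p + c(-1, 1) * z * sqrt(p * (1 - p) / n))
  ci <- pmin(pmax(ci, 0), 1)
  data.frame(name = name, estimate = p, ci_low = ci[1], ci_high = ci[2],
             successes = as.integer(successes), n = as.integer(n),
             ci_method = method, level = level, stringsAsFactors = FALSE)
}

#' Diagnostic accuracy metrics from a confusion matrix
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV
#' `tp/(tp+fp)`, NPV `tn/(tn+fn)` and prevalence `(tp+fn)/n`, each with a
#' binomial confidence interval. A metric whose denominator is zero is
#' reported with `NA` estimate and interval rather than raising an error
#' (e.g. specificity in an all-positive cohort).
#'
#' @param cm A [confusion_from_calls()] result.
#' @param ci_method,level Passed to [proportion_with_ci()].
#' @return data.frame, one row per metric, with the [proportion_with_ci()]
#'   columns plus `isup_threshold` and `cohort`.
#' @export
diagnostic_summary <- function(cm, ci_method = "wilson", level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  spec <- list(sensitivity = c(cm$tp, cm$tp + cm$fn),
               specificity = c(cm$tn, cm$tn + cm$fp),
               ppv = c(cm$tp, cm$tp + cm$fp),
               npv = c(cm$tn, cm$tn + cm$fn),
               prevalence = c(cm$tp + cm$fn, total))
  rows <- lapply(names(spec), function(nm) {
    sn <- spec[[nm]]
    if (sn[2] == 0)
      data.frame(name = nm, estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, successes = NA_integer_, n = 0L,
                 ci_method = ci_method, level = level, stringsAsFactors = FALSE)
    else
      proportion_with_ci(sn[1], sn[2], ci_method, level, name = nm)
  })
  out <- do.call(rbind, rows)
  out$isup_threshold <- cm$isup_threshold
  out$cohort <- cm$cohort
  out
}

#' Cohort diagnostic report
#'
#' Splits a call table by cohort tag and ISUP threshold, tallies each
#' confusion matrix and computes the accuracy metrics with confidence
#' intervals, group sizes and prevalence.
#'
#' @param calls Call table from [classify_cohort()].
#' @param thresholds Thresholds to report (default those present).
#' @param ci_method,level Passed to [diagnostic_summary()].
#' @return Object of class `diagnostic_report`: list with `metrics` (long
#'   data.frame), `confusions` (list of `confusion_matrix`), `groups`
#'   (per cohort x threshold positive/negative/excluded counts).
#' @export
cohort_report <- function(calls, thresholds = NULL, ci_method = "wilson",
                          level = 0.95) {
  if (!nrow(calls)) stop("empty call table")
  if (is.null(thresholds)) thresholds <- sort(unique(calls$isup_threshold))
  cohorts <- unique(calls$cohort)
  metrics <- list(); confusions <- list(); groups <- list()
  for (co in cohorts) {
    for (thr in thresholds) {
      sub <- calls[calls$cohort %in% co & calls$isup_threshold == thr, , drop = FALSE]
      if (!nrow(sub)) next
      cm <- confusion_from_calls(sub, thr)
      cm$cohort <- co
      key <- paste0(co, "_isup", thr)
      confusions[[key]] <- cm
      metrics[[key]] <- diagnostic_summary(cm, ci_method, level)
      groups[[key]] <- data.frame(
        cohort = co, isup_threshold = as.integer(thr),
        n_positive = cm$tp + cm$fn, n_negative = cm$tn + cm$fp,
        n_excluded = cm$n_excluded,
        n_total = cm$tp + cm$fn + cm$tn + cm$fp, stringsAsFactors = FALSE)
    }
  }
  structure(list(metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
                 confusions = confusions,
                 groups = do.call(rbind, c(groups, list(make.row.names = FALSE))),
                 ci_method = ci_method, level = level),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, digits = 2, ...) {
  cat("Patient-level diagnostic performance (", x$ci_method, " ",
      format(100 * x$level), "% CI)\n", sep = "")
  for (key in names(x$confusions)) {
    cm <- x$confusions[[key]]
    g <- x$groups[x$groups$cohort %in% cm$cohort &
                  x$groups$isup_threshold == cm$isup_threshold, ]
    cat(sprintf("\n%s cohort, ISUP >= %d (n+ = %d, n- = %d%s)\n",
                cm$cohort, cm$isup_threshold, g$n_positive, g$n_negative,
                if (g$n_excluded) sprintf(", excluded = %d", g$n_excluded) else ""))
    m <- x$metrics[x$metrics$cohort %in% cm$cohort &
                   x$metrics$isup_threshold == cm$isup_threshold, ]
    for (r in seq_len(nrow(m))) {
      if (is.na(m$estimate[r])) {
        cat(sprintf("  %-11s    --  (undefined: empty group)\n", m$name[r]))
      } else {
        cat(sprintf("  %-11s  %.*f (CI %.*f-%.*f)  [%d/%d]\n", m$name[r],
                    digits, m$estimate[r], digits, m$ci_low[r], digits,
                    m$ci_high[r], m$successes[r], m$n[r]))
      }
    }
  }
  invisible(x)
}

#' Format a proportion as a whole percentage
#'
#' Rendering convention for detection rates and prevalences: percentages are
#' printed to 0 decimals (`0.694 -> "69%"`); underlying values keep full
#' precision.
#' @param p Proportion in \[0, 1\].
#' @return Character like `"71%"`.
#' @export
format_percent <- function(p) sprintf("%.0f%%", 100 * p)

#' Write a diagnostic report to files
#'
#' Emits `report.csv` (long metric table), `report.json` (metrics, groups and
#' confusion counts) and `report.txt` (the printed rendering).
#'
#' @param report A [cohort_report()] result.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "report.csv")
  jsn <- file.path(out_dir, "report.json")
  txt <- file.path(out_dir, "report.txt")
  utils::write.csv(report$metrics, csv, row.names = FALSE)
  jsonlite::write_json(
    list(metrics = report$metrics, groups = report$groups,
         confusions = lapply(report$confusions, function(cm)
           cm[c("tp", "fp", "tn", "fn", "n_excluded", "isup_threshold", "cohort")]),
         ci_method = report$ci_method, level = report$level),
    jsn, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sink(txt); print(report); sink()
  invisible(c(csv = csv, json = jsn, txt = txt))
}
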