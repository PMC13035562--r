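fake_calls <- function(calls, threshold = 2L, cohort = "internal") {
  n <- length(calls)
  data.frame(patient_id = sprintf("p%03d", seq_len(n)), cohort = rep(cohort, n),
             isup_threshold = rep(as.integer(threshold), n),
             disease_positive = calls %in% c("TP", "FN"),
             model_detected = calls %in% c("TP", "FP"),
             biopsy_hit = calls == "TP", n_biopsies = rep(1L, n),
             max_hit_probability = rep(NA_real_, n), call = calls,
             stringsAsFactors = FALSE)
}

test_that("confusion_from_calls tallies correctly and rejects mixed thresholds", {
  cm <- confusion_from_calls(fake_calls(c("TP", "TP", "FN", "TN", "FP")), 2)
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(2, 1, 1, 1))

  empty <- confusion_from_calls(fake_calls(character(0)), 2)
  expect_equal(c(empty$tp, empty$fn, empty$tn, empty$fp), rep(0, 4))

  mixed <- rbind(fake_calls("TP", 2), fake_calls("TN", 3))
  expect_error(confusion_from_calls(mixed, 2), "mix")

  # excluded calls are dropped from every count
  cm2 <- confusion_from_calls(fake_calls(c("TP", "excluded", "TN")), 2)
  expect_equal(c(cm2$tp, cm2$tn, cm2$n_excluded), c(1, 1, 1))

  set.seed(21)
  draws <- sample(c("TP", "FP", "TN", "FN"), 1000, TRUE)
  cm3 <- confusion_from_calls(fake_calls(draws), 2)
  expect_equal(c(cm3$tp, cm3$fp, cm3$tn, cm3$fn),
               unname(c(sum(draws == "TP"), sum(draws == "FP"),
                        sum(draws == "TN"), sum(draws == "FN"))))
})

test_that("proportion_with_ci matches closed-form and library oracles", {
  # 59/85: the ISUP-2 detection-rate worked example, printed as 70%
  p <- proportion_with_ci(59, 85)
  expect_equal(p$estimate, 59 / 85)
  expect_equal(round(p$estimate, 3), 0.694)
  expect_equal(format_percent(round(p$estimate, 1)), "70%")

  # Wilson vs numeric inversion of the score test
  for (case in list(c(60, 100), c(0, 10), c(10, 10), c(145, 177))) {
    w <- proportion_with_ci(case[1], case[2], "wilson")
    o <- ref_wilson(case[1], case[2])
    expect_equal(c(w$ci_low, w$ci_high), o, tolerance = 1e-8)
  }
  expect_equal(proportion_with_ci(0, 10, "wilson")$ci_low, 0)

  # Clopper-Pearson vs binom.test
  for (case in list(c(60, 100), c(1, 20), c(93, 103))) {
    cp <- proportion_with_ci(case[1], case[2], "clopper-pearson")
    bt <- binom.test(case[1], case[2])$conf.int
    expect_equal(c(cp$ci_low, cp$ci_high), as.numeric(bt), tolerance = 1e-8)
  }

  # Wald is clipped to [0, 1] and all methods contain the point estimate
  wd <- proportion_with_ci(1, 30, "wald")
  expect_gte(wd$ci_low, 0)
  for (m in c("wilson", "clopper-pearson", "wald")) {
    r <- proportion_with_ci(60, 100, m)
    expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
  }
  expect_error(proportion_with_ci(5, 0), ">= 1")
  expect_error(proportion_with_ci(11, 10), "0..n")
})

test_that("diagnostic_summary computes the four metrics and leaves empty groups undefined", {
  mk <- function(tp, fn, tn, fp)
    confusion_from_calls(fake_calls(c(rep("TP", tp), rep("FN", fn),
                                      rep("TN", tn), rep("FP", fp))), 2)
  s <- diagnostic_summary(mk(59, 26, 0, 0))
  expect_equal(s$estimate[s$name == "sensitivity"], 59 / 85)
  expect_true(is.na(s$estimate[s$name == "specificity"]))

  perfect <- diagnostic_summary(mk(5, 0, 5, 0))
  expect_equal(perfect$estimate[perfect$name %in%
                                c("sensitivity", "specificity", "ppv", "npv")],
               rep(1, 4))

  s2 <- diagnostic_summary(mk(30, 10, 20, 20))
  expect_equal(s2$estimate[s2$name == "sensitivity"], 0.75)
  expect_equal(s2$estimate[s2$name == "specificity"], 0.5)
  expect_equal(s2$estimate[s2$name == "ppv"], 0.6)
  expect_equal(s2$estimate[s2$name == "npv"], 2 / 3)
  # sensitivity * (tp + fn) = tp exactly
  expect_identical(s2$estimate[s2$name == "sensitivity"] * 40, 30)
})

test_that("PPV/NPV respond to prevalence reweighting per Bayes' rule", {
  sens <- 0.9; spec <- 0.6
  for (mult in c(1, 3)) {  # negatives reweighted, sens/spec held fixed
    tp <- 90; fn <- 10; tn <- 60 * mult; fp <- 40 * mult
    s <- diagnostic_summary(confusion_from_calls(
      fake_calls(c(rep("TP", tp), rep("FN", fn), rep("TN", tn), rep("FP", fp))), 2))
    prev <- (tp + fn) / (tp + fn + tn + fp)
    ppv_bayes <- sens * prev / (sens * prev + (1 - spec) * (1 - prev))
    npv_bayes <- spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)
    expect_equal(s$estimate[s$name == "ppv"], ppv_bayes, tolerance = 1e-12)
    expect_equal(s$estimate[s$name == "npv"], npv_bayes, tolerance = 1e-12)
  }
})

test_that("cohort_report reproduces the printed group-size arithmetic", {
  # internal cohort composition: 73 non-RP, 84 ISUP2, 71 ISUP3, 1 ISUP4, 21 ISUP5
  grades <- c(rep(0, 73), rep(2, 84), rep(3, 71), rep(4, 1), rep(5, 21))
  thr_calls <- function(thr) {
    pos <- grades >= thr
    fake_calls(ifelse(pos, "TP", "TN"), thr)  # detection itself irrelevant here
  }
  calls <- rbind(thr_calls(2), thr_calls(3))
  rep <- cohort_report(calls)
  g <- rep$groups
  expect_equal(g$n_positive[g$isup_threshold == 2], 177)
  expect_equal(g$n_negative[g$isup_threshold == 2], 73)
  expect_equal(g$n_positive[g$isup_threshold == 3], 93)   # 71 + 1 + 21
  expect_equal(g$n_negative[g$isup_threshold == 3], 157)  # 73 + 84
  expect_equal(g$n_total, c(250, 250))

  prev2 <- rep$metrics[rep$metrics$isup_threshold == 2 &
                       rep$metrics$name == "prevalence", ]
  expect_equal(prev2$estimate, 177 / 250)
  expect_equal(format_percent(prev2$estimate), "71%")

  expect_error(cohort_report(calls[0, ]), "empty")

  d <- withr::local_tempdir()
  paths <- write_report(rep, d)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths["csv"])
  expect_equal(nrow(back), nrow(rep$metrics))
})

test_that("Wilson 95% coverage at p = 0.8, n = 177 sits in the calibrated band", {
  # quick version of the calibration suite (full 10^4-draw run in acceptance)
  set.seed(31)
  draws <- rbinom(2000, 177, 0.8)
  lo <- vapply(draws, function(k) proportion_with_ci(k, 177)$ci_low, numeric(1))
  hi <- vapply(draws, function(k) proportion_with_ci(k, 177)$ci_high, numeric(1))
  cover <- mean(lo <= 0.8 & 0.8 <= hi)
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})
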