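test_that("log-normal quantile fit honours the printed median and IQR shape", {
  fit <- lognormal_from_quantiles(47, 36, 74)
  expect_equal(exp(fit$meanlog), 47)            # median exact by construction
  set.seed(41)
  draws <- rlnorm(1e4, fit$meanlog, fit$sdlog)
  expect_gt(median(draws), 44); expect_lt(median(draws), 50)
  q <- quantile(draws, c(0.25, 0.75))
  expect_lt(abs(q[1] - 36) / 36, 0.10)          # quartiles within 10%
  expect_lt(abs(q[2] - 74) / 74, 0.10)
})

test_that("sample_prostate realizes the requested volume and is seed-deterministic", {
  cfg <- cohort_config(grid_shape = c(96, 96, 96))
  set.seed(42)
  g <- sample_prostate(cfg, volume_cc = 47)
  vol <- voxels_to_cc(sum(g$data), g)
  expect_lt(abs(vol - 47) / 47, 0.05)

  set.seed(7); a <- sample_prostate(cfg)
  set.seed(7); b <- sample_prostate(cfg)
  expect_identical(a$data, b$data)

  expect_error(sample_prostate(cohort_config(grid_shape = c(16, 16, 16)),
                               volume_cc = 47), "does not fit")
})

test_that("reference lesions are disjoint, in-gland, graded and volume-accurate", {
  cfg <- fast_cohort()
  set.seed(43)
  prost <- sample_prostate(cfg, volume_cc = 4)
  ann <- sample_reference_lesions(prost, 2, grades = c(3L, 2L),
                                  volumes_cc = c(0.3, 0.15))
  lm <- ann$labelmap$data
  expect_equal(sort(unique(as.integer(lm[lm > 0]))), c(1L, 2L))
  expect_identical(ann$grades, c(`1` = 3L, `2` = 2L))
  # inside the prostate, volumes within 10% of the request
  expect_true(all(prost$data[lm > 0] == 1L))
  v1 <- voxels_to_cc(sum(lm == 1L), ann$labelmap)
  v2 <- voxels_to_cc(sum(lm == 2L), ann$labelmap)
  expect_lt(abs(v1 - 0.3) / 0.3, 0.10)
  expect_lt(abs(v2 - 0.15) / 0.15, 0.10)

  # a 0.05 cc request stays below the 0.07 cc detectability cut
  set.seed(44)
  tiny <- sample_reference_lesions(prost, 1, grades = 3L, volumes_cc = 0.05)
  expect_lt(voxels_to_cc(sum(tiny$labelmap$data == 1L), tiny$labelmap), 0.07)
})

test_that("perfect fidelity reproduces the csPCa lesion union exactly", {
  cfg <- fast_cohort()
  set.seed(45)
  prost <- sample_prostate(cfg, volume_cc = 4)
  ann <- sample_reference_lesions(prost, 2, grades = c(3L, 1L),
                                  volumes_cc = c(0.3, 0.15))
  hm <- render_heatmap(ann, heatmap_fidelity())
  bin <- binarize_heatmap(hm, 0.5)
  # grade-1 lesion is NOT rendered; grade-3 lesion reproduced exactly
  expect_identical(bin$data == 1L, ann$labelmap$data == 1L)

  dead <- render_heatmap(ann, heatmap_fidelity(detection_probability = 0))
  expect_equal(sum(binarize_heatmap(dead, 0.5)$data), 0)
})

test_that("detection_probability drives the per-lesion rendering rate", {
  cfg <- fast_cohort()
  set.seed(46)
  prost <- sample_prostate(cfg, volume_cc = 4)
  ann <- sample_reference_lesions(prost, 1, grades = 3L, volumes_cc = 0.3)
  fid <- heatmap_fidelity(detection_probability = 0.7)
  hits <- vapply(1:2000, function(i) {
    hm <- render_heatmap(ann, fid)
    sum(hm$data) > 0
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.7), 0.03)  # binomial 3 sd at n = 2000 is 0.031
})

test_that("fidelity knobs degrade the heatmap in the advertised directions", {
  cfg <- fast_cohort()
  set.seed(47)
  prost <- sample_prostate(cfg, volume_cc = 4)
  ann <- sample_reference_lesions(prost, 1, grades = 3L, volumes_cc = 0.3)

  # localization offset displaces but keeps roughly the same foreground size
  off <- render_heatmap(ann, heatmap_fidelity(localization_offset_sd_mm = 4))
  moved <- binarize_heatmap(off, 0.5)$data == 1L
  orig <- ann$labelmap$data == 1L
  expect_gt(sum(moved), 0)
  expect_lt(sum(moved & orig), sum(orig))  # imperfect overlap after a 4 mm sd shift

  # false lesions appear without any reference lesion
  fl <- render_heatmap(NULL, heatmap_fidelity(false_lesion_rate = 3),
                       prostate = prost)
  expect_gt(sum(binarize_heatmap(fl, 0.5)$data), 0)

  # blur+noise keeps values in [0, 1]
  nz <- render_heatmap(ann, heatmap_fidelity(blur_sd_mm = 1, background_noise_sd = 0.05))
  expect_gte(min(nz$data), 0); expect_lte(max(nz$data), 1)
})

test_that("cohort plan composition follows prevalence and the grade mix", {
  cfg <- cohort_preset("internal", n_patients = 250, seed = 48,
                       grid_shape = c(40, 40, 40))
  plan <- cohort_plan(cfg)
  expect_equal(nrow(plan), 250)
  n_pos <- sum(plan$max_grade >= 2)
  expect_gte(n_pos, 150); expect_lte(n_pos, 200)  # 4 sd binomial band at p=.71

  big <- cohort_plan(cohort_preset("internal", n_patients = 4000, seed = 49))
  mix <- table(factor(big$max_grade[big$max_grade >= 2], levels = 2:5))
  expect_equal(as.numeric(mix / sum(mix)), c(84, 71, 1, 21) / 177, tolerance = 0.12)

  # same seed, same plan; patient substreams stable under cohort extension
  expect_identical(plan, cohort_plan(cfg))
  longer <- cohort_plan(cohort_preset("internal", n_patients = 260, seed = 48,
                                      grid_shape = c(40, 40, 40)))
  expect_identical(plan, longer[1:250, ])
})

test_that("build_patient is deterministic and consistent with the plan", {
  cfg <- fast_cohort(n = 6, seed = 50)
  plan <- cohort_plan(cfg)
  for (i in c(1L, 3L)) {
    p1 <- build_patient(cfg, heatmap_fidelity(), i)
    p2 <- build_patient(cfg, heatmap_fidelity(), i)
    expect_identical(p1$heatmap$data, p2$heatmap$data)
    expect_equal(p1$arm, plan$arm[i])
    if (p1$arm == "RP")
      expect_equal(max_isup_grade(p1$annotation), plan$max_grade[i])
  }
})

test_that("generate_cohort writes a readable, byte-reproducible cohort", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- fast_cohort(n = 6, seed = 51)
  m1 <- generate_cohort(cfg, heatmap_fidelity(), d1)
  m2 <- generate_cohort(cfg, heatmap_fidelity(), d2)

  man <- read_manifest(m1)
  expect_equal(nrow(man), 6)
  files <- sort(setdiff(list.files(d1), "provenance.json"))
  expect_identical(files, sort(setdiff(list.files(d2), "provenance.json")))
  h1 <- tools::md5sum(file.path(d1, files)); h2 <- tools::md5sum(file.path(d2, files))
  expect_identical(unname(h1), unname(h2))  # byte-identical volumes + manifest

  # volumes round-trip through the declared readers
  hm <- read_volume(file.path(d1, man$heatmap_path[1]), "heatmap")
  expect_equal(dim(hm$data), c(40L, 40L, 40L))
  rp <- which(man$arm == "RP")[1]
  if (!is.na(rp)) {
    ann <- load_annotation(man, man$patient_id[rp])
    expect_s3_class(ann, "reference_annotation")
    expect_gte(max_isup_grade(ann), 2L)
  }
})
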