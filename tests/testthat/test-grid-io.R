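test_that("voxel_grid enforces its invariants", {
  expect_error(voxel_grid(matrix(0, 3, 3), kind = "heatmap"), "3D")
  expect_error(voxel_grid(array(0, c(3, 3, 3)), spacing_mm = -1), "positive")
  expect_error(voxel_grid(array(1.5, c(2, 2, 2)), kind = "heatmap"), "outside")
  expect_error(voxel_grid(array(-0.3, c(2, 2, 2)), kind = "labelmap"), "non-negative")
  expect_error(voxel_grid(array(0.5, c(2, 2, 2)), kind = "labelmap"), "integer")

  g <- voxel_grid(array(0, c(4, 5, 6)), kind = "heatmap")
  expect_equal(g$spacing_mm, rep(0.75, 3))
  expect_equal(voxel_volume_mm3(g), 0.75^3)
  expect_equal(voxels_to_cc(1, g), 0.75^3 / 1000)
  expect_equal(needle_axis(g), 3L)
  g2 <- voxel_grid(array(0, c(4, 5, 6)), axes = c("SI", "LR", "AP"), kind = "mask")
  expect_equal(needle_axis(g2), 1L)
})

test_that("NIfTI round trip is identity on labelmaps and <= 1e-7 on heatmaps", {
  d <- withr::local_tempdir()

  zero <- voxel_grid(array(0, c(10, 10, 10)), kind = "heatmap")
  write_volume(zero, file.path(d, "zero.nii"))
  back <- read_volume(file.path(d, "zero.nii"), "heatmap")
  expect_equal(back$data, zero$data)
  expect_equal(back$spacing_mm, zero$spacing_mm)

  set.seed(42)
  hm <- voxel_grid(array(runif(9 * 11 * 7), c(9, 11, 7)), spacing_mm = 0.75,
                   kind = "heatmap")
  for (ext in c("rt.nii", "rt.nii.gz")) {
    write_volume(hm, file.path(d, ext))
    rt <- read_volume(file.path(d, ext), "heatmap")
    expect_lt(max(abs(rt$data - hm$data)), 1e-7)
  }

  lm <- voxel_grid(array(sample(c(0L, 1L, 2L, 255L), 6^3, TRUE), c(6, 6, 6)),
                   kind = "labelmap")
  write_volume(lm, file.path(d, "lab.nii.gz"))
  rt <- read_volume(file.path(d, "lab.nii.gz"), "labelmap")
  expect_identical(rt$data, lm$data)
})

test_that("read_volume rejects bad inputs and warns on odd spacing", {
  d <- withr::local_tempdir()
  expect_error(read_volume(file.path(d, "nope.nii"), "heatmap"), "not found")

  # heatmap with a value outside [0, 1] is rejected at read time
  bad <- voxel_grid(array(255L, c(3, 3, 3)), kind = "labelmap")
  write_volume(bad, file.path(d, "bad.nii"))
  expect_error(read_volume(file.path(d, "bad.nii"), "heatmap"), "outside")

  aniso <- voxel_grid(array(0L, c(3, 3, 3)), spacing_mm = c(0.5, 0.5, 1.0),
                      kind = "mask")
  write_volume(aniso, file.path(d, "aniso.nii"))
  expect_warning(rt <- read_volume(file.path(d, "aniso.nii"), "mask"), "anisotropic")
  expect_equal(rt$spacing_mm, c(0.5, 0.5, 1.0), tolerance = 1e-6)

  # not a NIfTI file
  writeBin(as.raw(rep(1:200, 2)), file.path(d, "junk.nii"))
  expect_error(read_volume(file.path(d, "junk.nii"), "mask"), "NIfTI")
})

test_that("our NIfTI dialect interoperates with nibabel", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  d <- withr::local_tempdir()
  set.seed(7)
  hm <- voxel_grid(array(round(runif(5 * 6 * 7), 3), c(5, 6, 7)), kind = "heatmap")
  ours <- file.path(d, "ours.nii.gz")
  write_volume(hm, ours)
  # nibabel reads our file: check shape, zooms and checksum
  out <- system2("python", c("-c", shQuote(sprintf(
    "import nibabel as nib, numpy as np; im = nib.load('%s'); print(im.shape); print(tuple(float(z) for z in im.header.get_zooms())); print(float(np.abs(im.get_fdata()).sum()))",
    ours))), stdout = TRUE)
  expect_equal(out[1], "(5, 6, 7)")
  expect_equal(out[2], "(0.75, 0.75, 0.75)")
  expect_equal(as.numeric(out[3]), sum(hm$data), tolerance = 1e-5)

  # we read a file nibabel wrote (float64, different spacing)
  theirs <- file.path(d, "theirs.nii.gz")
  system2("python", c("-c", shQuote(sprintf(
    "import nibabel as nib, numpy as np; a = np.arange(24, dtype=np.float64).reshape(2, 3, 4, order='F') / 24; img = nib.Nifti1Image(a, np.diag([0.5, 0.5, 0.5, 1])); img.header.set_zooms((0.5, 0.5, 0.5)); nib.save(img, '%s')",
    theirs))))
  rt <- read_volume(theirs, "heatmap")
  expect_equal(dim(rt$data), c(2L, 3L, 4L))
  expect_equal(rt$spacing_mm, rep(0.5, 3), tolerance = 1e-6)
  expect_equal(rt$data, array((0:23) / 24, c(2, 3, 4)), tolerance = 1e-12)
})

test_that("manifest parsing is validating, total and order-preserving", {
  d <- withr::local_tempdir()
  df <- data.frame(
    patient_id = c("B", "A", "C"), arm = c("RP", "RP", "non-RP"),
    cohort = "internal",
    heatmap_path = paste0(c("B", "A", "C"), "_h.nii"),
    annotation_path = c("B_l.nii", "A_l.nii", ""),
    grades_path = c("B_g.json", "A_g.json", ""))
  p <- file.path(d, "m.csv")
  write_manifest(df, p)
  m <- read_manifest(p)
  expect_equal(nrow(m), 3L)
  expect_equal(m$patient_id, c("B", "A", "C"))  # file order kept
  expect_equal(m$arm, df$arm)

  # JSON dialect reads identically
  jsonlite::write_json(df, file.path(d, "m.json"))
  mj <- read_manifest(file.path(d, "m.json"))
  expect_equal(mj$patient_id, m$patient_id)

  dup <- df; dup$patient_id <- c("A", "A", "C")
  write_manifest(dup, p)
  expect_error(read_manifest(p), "duplicate")

  noann <- df; noann$annotation_path[1] <- ""; noann$grades_path[1] <- ""
  write_manifest(noann, p)
  expect_error(read_manifest(p), "without annotation")

  badarm <- df; badarm$arm[3] <- "control"
  write_manifest(badarm, p)
  expect_error(read_manifest(p), "arm")
})

test_that("grade sidecars and annotations validate label/grade consistency", {
  d <- withr::local_tempdir()
  jsonlite::write_json(list(`1` = 3, `2` = 2), file.path(d, "g.json"),
                       auto_unbox = TRUE)
  g <- read_grades(file.path(d, "g.json"))
  expect_identical(g, c(`1` = 3L, `2` = 2L))
  jsonlite::write_json(list(`1` = 7), file.path(d, "bad.json"), auto_unbox = TRUE)
  expect_error(read_grades(file.path(d, "bad.json")), "1..5")

  arr <- array(0L, c(4, 4, 4))
  arr[1:2, 1:2, 1:2] <- 1L
  arr[4, 4, 4] <- 2L
  lm <- voxel_grid(arr, kind = "labelmap")
  expect_error(reference_annotation(lm, c(`1` = 3L)), "must match")
  ann <- reference_annotation(lm, c(`1` = 3L, `2` = 2L))
  expect_equal(max_isup_grade(ann), 3L)
  expect_equal(max_isup_grade(NULL), 0L)

  # a label split into two components violates the connectedness invariant
  arr2 <- arr
  arr2[4, 4, 4] <- 1L
  expect_error(reference_annotation(voxel_grid(arr2, kind = "labelmap"),
                                    c(`1` = 3L)), "connected")
})
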