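# Independent brute-force oracles and small fixture builders.
# Oracles deliberately share no code with the implementation paths they check.

# flood-fill component labeling in plain R (small grids only)
ref_label_components <- function(arr, connectivity = 26) {
  dm <- dim(arr)
  lab <- array(0L, dm)
  nextl <- 0L
  nbrs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  man <- abs(nbrs$di) + abs(nbrs$dj) + abs(nbrs$dk)
  maxman <- c(`6` = 1, `18` = 2, `26` = 3)[[as.character(connectivity)]]
  nbrs <- nbrs[man >= 1 & man <= maxman, ]
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    if (!arr[i, j, k] || lab[i, j, k] != 0L) next
    nextl <- nextl + 1L
    queue <- list(c(i, j, k))
    lab[i, j, k] <- nextl
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(nbrs))) {
        w <- v + c(nbrs$di[r], nbrs$dj[r], nbrs$dk[r])
        if (any(w < 1) || any(w > dm)) next
        if (arr[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nextl
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
  }
  lab
}

# per-pixel OR projection by explicit loops
ref_project <- function(arr, axis) {
  keep <- setdiff(1:3, axis)
  dm <- dim(arr)
  out <- matrix(FALSE, dm[keep[1]], dm[keep[2]])
  for (a in seq_len(dm[keep[1]])) for (b in seq_len(dm[keep[2]])) {
    idx <- c(NA, NA, NA)
    idx[keep] <- c(a, b)
    for (t in seq_len(dm[axis])) {
      idx[axis] <- t
      if (arr[idx[1], idx[2], idx[3]]) { out[a, b] <- TRUE; break }
    }
  }
  out
}

# Wilson interval by numerically inverting the score test (oracle for the
# closed-form implementation)
ref_wilson <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  ph <- x / n
  f <- function(p) (ph - p)^2 - z^2 * p * (1 - p) / n
  lo <- if (ph == 0) 0 else
    uniroot(f, c(1e-9, if (ph == 1) 1 - 1e-9 else ph), tol = 1e-12)$root
  hi <- if (ph == 1) 1 else
    uniroot(f, c(if (ph == 0) 1e-9 else ph, 1 - 1e-9), tol = 1e-12)$root
  c(lo, hi)
}

# -- fixture builders ---------------------------------------------------------

cube_mask <- function(dm, lo, size, spacing = 0.75) {
  a <- array(0L, dm)
  a[lo[1]:(lo[1] + size[1] - 1), lo[2]:(lo[2] + size[2] - 1),
    lo[3]:(lo[3] + size[3] - 1)] <- 1L
  voxel_grid(a, spacing_mm = spacing, kind = "mask")
}

fp_from_matrix <- function(m, pixel_area = 0.5625) {
  structure(list(mask = m, pixel_area_mm2 = pixel_area, plane_axes = c(1L, 2L)),
            class = "footprint2d")
}

# random blobby footprint: union of a few discs on an nr x nc plane
random_blob_fp <- function(nr = 40, nc = 40, n_discs = 3, rmax = 8) {
  m <- matrix(FALSE, nr, nc)
  for (d in seq_len(n_discs)) {
    cx <- runif(1, rmax, nr - rmax); cy <- runif(1, rmax, nc - rmax)
    r <- runif(1, 2, rmax)
    g <- expand.grid(i = 1:nr, j = 1:nc)
    m[as.matrix(g[ (g$i - cx)^2 + (g$j - cy)^2 <= r^2, ])] <- TRUE
  }
  fp_from_matrix(m)
}

# annotation with axis-aligned box lesions; spec: list(lo=, size=, grade=)
toy_annotation <- function(dm = c(24, 24, 24), lesions = list(), spacing = 0.75,
                           prostate = NULL) {
  lm <- array(0L, dm)
  grades <- integer(0)
  for (s in seq_along(lesions)) {
    L <- lesions[[s]]
    sz <- rep(L$size, length.out = 3)
    lm[L$lo[1]:(L$lo[1] + sz[1] - 1), L$lo[2]:(L$lo[2] + sz[2] - 1),
       L$lo[3]:(L$lo[3] + sz[3] - 1)] <- s
    grades[as.character(s)] <- L$grade
  }
  reference_annotation(voxel_grid(lm, spacing_mm = spacing, kind = "labelmap"),
                       grades, prostate_mask = prostate, check = FALSE)
}

# lesion objects straight from a mask grid
lesions_from_mask <- function(mask, connectivity = 26)
  extract_candidate_lesions(mask, connectivity)

# heatmap that binarizes (at 0.5) exactly to the given mask grid
heatmap_from_mask <- function(mask, peak = 0.95) {
  voxel_grid(array(ifelse(mask$data > 0, peak, 0), dim(mask$data)),
             spacing_mm = mask$spacing_mm, kind = "heatmap")
}

# small fast cohort for pipeline tests: 40^3 grid, small prostate
fast_cohort <- function(n = 10, seed = 11, ...) {
  cohort_config(n_patients = n, seed = seed,
                grid_shape = c(40, 40, 40),
                prostate_volume = list(meanlog = log(4), sdlog = 0.15),
                lesion_volume = list(meanlog = log(0.2), sdlog = 0.3),
                ...)
}
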