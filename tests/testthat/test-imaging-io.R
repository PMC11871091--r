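test_that("image serialization round-trips within HU quantization", {
  s <- noisy_sample64()
  d <- withr::local_tempdir()
  for (ext in c(".nii", ".nii.gz")) {
    f <- file.path(d, paste0("img", ext))
    write_image(s$image, f)
    back <- read_image(f)
    expect_lt(max(abs(back$values - s$image$values)), 0.5)
    expect_equal(back$pixel_spacing, s$image$pixel_spacing)
    expect_equal(back$slice_thickness, s$image$slice_thickness)
    expect_identical(dim(back$values), dim(s$image$values))
  }
})

test_that("3-D stacks round-trip with slice order preserved", {
  s <- clean_stack64()
  d <- withr::local_tempdir()
  f <- file.path(d, "stack.nii.gz")
  write_image(s$image, f)
  back <- read_image(f)
  expect_identical(dim(back$values), dim(s$image$values))
  expect_lt(max(abs(back$values - s$image$values)), 0.5)
  fm <- file.path(d, "stack_mask.nii")
  write_mask(s$labels, fm)
  expect_identical(read_mask(fm)$classes, s$labels$classes)
})

test_that("missing spacing metadata is an explicit error, not a default", {
  d <- withr::local_tempdir()
  f <- file.path(d, "nospacing.nii")
  hipseg:::write_nifti(matrix(0, 8, 8), f, spacing = c(NA, NA), thickness = 3)
  expect_error(read_image(f), "spacing")
})

test_that("unknown extensions are rejected", {
  img <- ct_image(matrix(0, 8, 8), 1)
  expect_error(write_image(img, "x.png"), "unsupported image format")
  expect_error(read_image("x.dcm"), "unsupported image format")
})

test_that("calibration recovers a known line exactly from noise-free rods", {
  # rods generated from density = (HU - 10) / 1.25, i.e. HU = 1.25 d + 10
  n <- 64
  img <- matrix(-1000, n, n)
  rois <- list()
  nominal <- c(150, 75, 0)
  for (r in 1:3) {
    roi <- matrix(FALSE, n, n)
    roi[(r * 12):(r * 12 + 5), 10:15] <- TRUE
    img[roi] <- 1.25 * nominal[r] + 10
    rois[[r]] <- roi
  }
  ci <- ct_image(img, 1)
  fit <- fit_calibration(ci, rois, nominal)
  expect_lt(abs(fit$slope - 1 / 1.25) / (1 / 1.25), 1e-9)
  expect_lt(abs(fit$intercept - (-10 / 1.25)), 1e-9)
  expect_equal(fit$r_squared, 1)
  # densest rod maps back to exactly its nominal concentration
  dens <- apply_calibration(ci, fit)
  expect_equal(mean(dens$values[rois[[1]]]), 150, tolerance = 1e-12)
})

test_that("two rods reproduce the interpolating line exactly", {
  img <- matrix(0, 16, 16)
  r1 <- matrix(FALSE, 16, 16); r1[2:4, 2:4] <- TRUE
  r2 <- matrix(FALSE, 16, 16); r2[10:12, 10:12] <- TRUE
  img[r1] <- 200; img[r2] <- 40
  fit <- fit_calibration(ct_image(img, 1), list(r1, r2), c(150, 30))
  expect_equal(fit$slope, (150 - 30) / (200 - 40), tolerance = 1e-12)
  expect_equal(fit$intercept, 30 - fit$slope * 40, tolerance = 1e-9)
})

test_that("degenerate and invalid calibration inputs error", {
  img <- matrix(100, 16, 16)
  r1 <- matrix(FALSE, 16, 16); r1[2:4, 2:4] <- TRUE
  r2 <- matrix(FALSE, 16, 16); r2[10:12, 10:12] <- TRUE
  ci <- ct_image(img, 1)
  expect_error(fit_calibration(ci, list(r1, r2), c(150, 75)), "degenerate")
  expect_error(fit_calibration(ci, list(r1), 150), "at least 2")
  expect_error(fit_calibration(ci, list(r1, r1), c(150, 75)), "disjoint")
})

test_that("noisy rods recover the slope within 3 standard errors", {
  # Monte-Carlo over seeds: with sigma = 5 HU noise on 1000-pixel ROIs the
  # empirical slope distribution must be centred on the generating slope.
  set.seed(99)
  n <- 96
  rois <- lapply(1:3, function(r) {
    roi <- matrix(FALSE, n, n)
    roi[((r - 1) * 32 + 1):((r - 1) * 32 + 25), 1:40] <- TRUE  # 1000 px
    roi
  })
  nominal <- c(150, 75, 0)
  true_slope <- 1 / 1.2          # density per HU; rods at HU = 1.2 * density
  slopes <- vapply(seq_len(200), function(rep) {
    img <- matrix(-1000, n, n)
    for (r in 1:3)
      img[rois[[r]]] <- 1.2 * nominal[r] + rnorm(1000, 0, 5)
    fit_calibration(ct_image(img, 1), rois, nominal)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - true_slope), 3 * se)
})

test_that("apply_calibration is the elementwise affine map", {
  set.seed(1)
  v <- matrix(rnorm(64, 0, 300), 8, 8)
  fit <- structure(list(slope = 0.8, intercept = -12), class = "calibration_fit")
  out <- apply_calibration(ct_image(v, 1), fit)
  expect_equal(out$values, 0.8 * v - 12, tolerance = 1e-12)
})
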