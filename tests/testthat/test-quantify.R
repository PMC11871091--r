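test_that("reference slice maximizes the bone-thickness proxy", {
  s <- clean_stack64()                       # bone area peaks at the centre
  ref <- select_reference_slice(s$image, s$labels)
  expect_equal(ref, 3L)
  # constant stack: inferior-most (largest index) wins the tie
  cls <- s$labels$classes
  for (i in 2:5) cls[, , i] <- cls[, , 1]
  const <- label_mask(cls, s$labels$pixel_spacing, s$labels$slice_thickness)
  expect_equal(select_reference_slice(NULL, const), 5L)
  # jittered stack equals the brute-force argmax of per-slice counts
  set.seed(13)
  jit <- cls
  for (i in 1:5) {
    sl <- jit[, , i]
    drop_n <- sample(0:40, 1)
    bone_px <- which(sl == 1L | sl == 2L)
    sl[sample(bone_px, min(drop_n, length(bone_px)))] <- 0L
    jit[, , i] <- sl
  }
  jm <- label_mask(jit, s$labels$pixel_spacing, s$labels$slice_thickness)
  cols <- (ncol(jit[, , 1]) %/% 2 + 1):ncol(jit[, , 1])
  counts <- sapply(1:5, function(i) sum(jit[, cols, i] %in% c(1L, 2L)))
  expect_equal(select_reference_slice(NULL, jm),
               max(which(counts == max(counts))))
  # no bone anywhere is an error
  none <- label_mask(array(0L, dim(cls)), 1)
  expect_error(select_reference_slice(NULL, none), "no bone")
})

test_that("areas convert pixel counts to cm^2", {
  m <- matrix(0L, 20, 20)
  m[1:10, 1:10] <- 5L                        # 100 pixels
  lm1 <- label_mask(m, pixel_spacing = 1)    # 1x1 mm pixels
  expect_equal(tissue_area(lm1, 5L), 1.0)
  expect_equal(tissue_area(lm1, 4L), 0)      # empty class
  # scale equivariance: area scales with spacing^2
  lm2 <- label_mask(m, pixel_spacing = 2)
  expect_equal(tissue_area(lm2, 5L), 4 * tissue_area(lm1, 5L))
  lm_na <- label_mask(m, pixel_spacing = NA)
  expect_error(tissue_area(lm_na, 5L), "spacing")
})

test_that("rasterized disc area is within 2% of the analytic value", {
  n <- 200
  i <- matrix(seq_len(n), n, n); j <- t(i)
  disc <- (i - 100.3)^2 + (j - 99.6)^2 <= 20^2   # radius 20 mm at 1 mm px
  m <- matrix(0L, n, n); m[disc] <- 5L
  area <- tissue_area(label_mask(m, 1), 5L)
  expect_lt(abs(area - pi * 4) / (pi * 4), 0.02)  # pi * (2 cm)^2
})

test_that("volumes sum slice areas times thickness", {
  # constant cross-section: 10 cm^2 per slice, 5 slices, 3 mm -> 15 cm^3
  m <- array(0L, c(40, 40, 5))
  m[1:25, 1:40, ] <- 5L                      # 1000 px * 1 mm^2 = 10 cm^2
  lm <- label_mask(m, pixel_spacing = 1, slice_thickness = 3)
  expect_equal(tissue_volume(lm, 5L), 15)
  expect_equal(tissue_volume(lm, 4L), 0)
  # varying areas equal the brute-force per-slice sum
  set.seed(7)
  for (s in 1:5) {
    k <- sample(100:900, 1)
    sl <- matrix(0L, 40, 40); sl[sample(1600, k)] <- 5L
    m[, , s] <- sl
  }
  lm <- label_mask(m, pixel_spacing = 1, slice_thickness = 3)
  brute <- sum(sapply(1:5, function(s) sum(m[, , s] == 5L))) * 0.01 * 0.3
  expect_equal(tissue_volume(lm, 5L), brute)
  # volume is linear in thickness
  lm2 <- label_mask(m, pixel_spacing = 1, slice_thickness = 6)
  expect_equal(tissue_volume(lm2, 5L), 2 * tissue_volume(lm, 5L))
  # window must fit in the stack
  expect_error(tissue_volume(lm, 5L, reference = 2), "window")
})

test_that("ahu and the height adjustment follow their definitions", {
  v <- matrix(-1000, 16, 16)
  m <- matrix(0L, 16, 16)
  m[4:8, 4:8] <- 5L
  v[m == 5L] <- 50
  img <- ct_image(v, 1); lm <- label_mask(m, 1)
  a <- ahu(img, lm, 5L)
  expect_equal(a$ahu, 50)
  a2 <- ahu(img, lm, 5L, height_m = 1.7)
  expect_equal(a2$ahu_per_h2, 50 / 2.89, tolerance = 1e-12)
  expect_error(ahu(img, lm, 4L), "empty")
  # mixture matches the weighted-mean oracle on a noise-free phantom
  s <- clean_sample64()
  am <- ahu(s$image, s$labels, 5L)
  px <- s$labels$classes == 5L
  expect_equal(am$ahu, sum(s$image$values[px]) / sum(px), tolerance = 1e-12)
})

test_that("marrow ratios are complementary fractions of TBM", {
  m <- matrix(0L, 20, 20)
  m[1:12, 1:20] <- 3L                        # HBM: 240 px
  m[13:16, 1:20] <- 4L                       # MAT:  80 px
  r <- marrow_ratios(label_mask(m, 1))
  expect_equal(unname(r), c(0.75, 0.25))
  m[m == 4L] <- 3L
  expect_equal(unname(marrow_ratios(label_mask(m, 1))), c(1, 0))
  m[] <- 0L
  expect_true(all(is.na(marrow_ratios(label_mask(m, 1)))))
  # complements sum to one exactly on random masks
  set.seed(5)
  for (rep in 1:25) {
    mm <- matrix(sample(0:7, 400, replace = TRUE), 20, 20)
    r <- marrow_ratios(label_mask(mm, 1))
    if (!anyNA(r)) expect_identical(unname(sum(r)), 1)
  }
})

test_that("phantom areas equal generator pixel counts exactly", {
  s <- clean_sample64()
  px_area_cm2 <- prod(s$labels$pixel_spacing) / 100
  for (k in 1:7)
    expect_equal(tissue_area(s$labels, k),
                 sum(s$labels$classes == k) * px_area_cm2)
})

test_that("quantify_subject assembles the full report row", {
  s <- clean_stack64()
  row <- quantify_subject(s$image, s$labels, height_m = s$meta$height_m,
                          subject_id = s$meta$subject_id)
  expect_equal(row$reference_slice, 3)
  expect_equal(row$tbm_area, row$area_hbm + row$area_mat)
  expect_equal(row$hbm_over_tbm + row$mat_over_tbm, 1)
  expect_equal(row$ahu_muscle_per_h2,
               row$ahu_muscle / s$meta$height_m^2)
  # volume of the reference tissue equals the brute-force slice sum
  ref <- row$reference_slice
  areas <- sapply((ref - 2):(ref + 2),
                  function(i) tissue_area(s$labels, 5L, i))
  expect_equal(row$volume_muscle, sum(areas) * 0.3)
  tab <- quantify_cohort(list(s))
  expect_equal(nrow(tab), 1)
})
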