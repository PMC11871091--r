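test_that("dsc matches the formula on constructed cases", {
  m <- matrix(0L, 4, 4)
  m[1:2, 1:2] <- 1L
  expect_equal(dsc(m, m, 1L), 100)
  expect_equal(dsc(m, m, 1L, scale = "unit"), 1)
  a <- matrix(0L, 4, 4); b <- matrix(0L, 4, 4)
  a[1, 1:4] <- 1L                       # |A| = 4
  b[1, 3:4] <- 1L; b[2, 1:2] <- 1L      # |B| = 4, overlap 2
  expect_equal(dsc(a, b, 1L), 50)
  expect_true(is.na(dsc(a, b, 5L)))     # both empty -> undefined
  expect_error(dsc(a, matrix(0L, 3, 3), 1L), "shapes differ")
})

test_that("metrics match brute-force oracles on 200 random mask pairs", {
  set.seed(2024)
  for (rep in seq_len(200)) {
    n <- sample(12:64, 1)
    pair <- random_mask_pair(n)
    k <- sample(1:3, 1)
    expect_equal(dsc(pair$a, pair$b, k),
                   oracle_dsc(pair$a, pair$b, k), tolerance = 1e-12)
    ss <- sensitivity_specificity(pair$a, pair$b, k)
    os <- oracle_sens_spec(pair$a, pair$b, k)
    expect_identical(unname(ss), os)
    av <- assd(pair$a, pair$b, k, spacing = c(1, 1))
    ov <- oracle_assd(pair$a, pair$b, k)
    if (is.na(ov)) expect_true(is.na(av))
    else expect_lt(abs(av - ov), 1e-9)
  }
})

test_that("dsc is symmetric; sensitivity/specificity are not", {
  set.seed(3)
  asym_seen <- FALSE
  for (rep in 1:20) {
    pair <- random_mask_pair(24)
    for (k in 1:3) {
      expect_identical(dsc(pair$a, pair$b, k), dsc(pair$b, pair$a, k))
      d <- dsc(pair$a, pair$b, k)
      if (!is.na(d)) expect_lte(d, 100)
      s1 <- sensitivity_specificity(pair$a, pair$b, k)
      s2 <- sensitivity_specificity(pair$b, pair$a, k)
      if (!isTRUE(all.equal(s1, s2))) asym_seen <- TRUE
      a1 <- assd(pair$a, pair$b, k); a2 <- assd(pair$b, pair$a, k)
      if (!is.na(a1)) expect_equal(a1, a2)
    }
  }
  expect_true(asym_seen)
})

test_that("assd handles constructed geometries and spacing", {
  m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
  expect_equal(assd(m, m, 1L, spacing = c(1, 1)), 0)
  a <- matrix(0L, 8, 8); b <- matrix(0L, 8, 8)
  a[4, 2] <- 1L; b[4, 5] <- 1L          # 3 pixels apart
  expect_equal(assd(a, b, 1L, spacing = c(1, 1)), 3)
  expect_equal(assd(a, b, 1L, spacing = c(2, 2)), 6)   # spacing scales mm
  expect_true(is.na(assd(a, matrix(0L, 8, 8), 1L, spacing = c(1, 1))))
})

test_that("sensitivity/specificity follow the confusion counts", {
  truth <- matrix(1L, 5, 2)
  pred <- matrix(1L, 5, 2)
  pred[c(9, 10)] <- 0L                  # TP = 8, FN = 2
  ss <- sensitivity_specificity(truth, pred, 1L)
  expect_equal(ss[["sensitivity"]], 80)
  expect_true(is.na(ss[["specificity"]]))  # no true negatives exist
  expect_equal(unname(sensitivity_specificity(pred, pred, 1L)), c(100, 100))
})

test_that("cv plans partition subjects with near-equal folds", {
  ids <- sprintf("s%02d", 1:23)
  plan <- make_cv_plan(ids, k = 10, seed = 1)
  expect_setequal(plan$subject_id, ids)
  sizes <- table(plan$fold)
  expect_lte(diff(range(sizes)), 1)
  expect_identical(make_cv_plan(ids, 10, seed = 1)$fold, plan$fold)
  expect_error(make_cv_plan(ids, k = 24), "k must lie")
  expect_error(make_cv_plan(c("a", "a"), 2), "unique")
})

test_that("run_cv with k=2 on 4 subjects makes two folds of two", {
  co <- generate_cohort(cfg64(seed = 71), 4)
  rep <- run_cv(co, k = 2, oracle_model_factory(), train_config(seed = 1))
  expect_identical(sort(as.integer(table(rep$plan$fold))), c(2L, 2L))
  expect_equal(unique(rep$summary$dsc_mean), 100)
  expect_true(all(rep$summary$dsc_sd == 0))
  expect_true(all(table(rep$per_image$subject_id) == 7))  # 7 classes once
})

test_that("cross-domain evaluation reports both domains and deltas", {
  cfg <- cfg64(seed = 81, domain_shift = list(hu_offset = 0,
                                              spacing_factor = 1))
  co <- generate_cohort(cfg, 8, domains = c("A", "B"))
  rep <- cross_domain_eval(function(s) refseg(s$image), co)
  expect_setequal(names(rep$per_domain), c("A", "B"))
  expect_equal(nrow(rep$delta), 7)
  expect_equal(nrow(rep$per_domain$A), 7)
  # zero configured shift: domains are exchangeable, deltas small
  expect_lt(abs(rep$mean_dsc[["A"]] - rep$mean_dsc[["B"]]), 2)
  onlyA <- co[vapply(co, function(s) s$meta$domain, character(1)) == "A"]
  expect_error(cross_domain_eval(function(s) refseg(s$image), onlyA),
               "both domains")
})

test_that("report aggregation means per fold then across folds", {
  co <- generate_cohort(cfg64(seed = 91), 6)
  rep <- run_cv(co, k = 3, refseg_model_factory(), train_config(seed = 2))
  expect_equal(nrow(rep$summary), 7)
  expect_equal(sort(unique(rep$fold_summary$fold)), 1:3)
  # cross-check one cell against a direct computation
  f1 <- rep$per_image[rep$per_image$fold == 1 & rep$per_image$class == 5, ]
  expect_equal(
    rep$fold_summary$dsc[rep$fold_summary$fold == 1 &
                           rep$fold_summary$class == 5],
    mean(f1$dsc, na.rm = TRUE))
  expect_true(all(is.finite(rep$timing$seconds_per_slice)))
})
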