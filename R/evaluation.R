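# Segmentation metrics, k-fold cross-validation and the cross-domain
# robustness experiment.

as_class_grid <- function(x) {
  if (inherits(x, "label_mask")) x$classes else x
}

mask_spacing <- function(x) {
  if (inherits(x, "label_mask")) x$pixel_spacing else c(NA_real_, NA_real_)
}

#' Dice similarity coefficient for one class
#'
#' `DSC(A, B) = 2|A intersect B| / (|A| + |B|)` on the binarized class,
#' reported as a percentage by default (the reporting convention of the
#' protocol) or on the 0-1 scale. Symmetric in its arguments. If the class is
#' empty in both masks the DSC is undefined and `NA` is returned (flagged and
#' excluded from aggregation, never counted as perfect agreement).
#'
#' @param a,b [label_mask()]s or integer class grids of equal shape.
#' @param class_code Tissue code (1..7) to binarize on.
#' @param scale `"percent"` (default) or `"unit"`.
#' @return Numeric scalar (percentage or fraction), `NA` if undefined.
#' @export
dsc <- function(a, b, class_code, scale = c("percent", "unit")) {
  scale <- match.arg(scale)
  a <- as_class_grid(a); b <- as_class_grid(b)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a == class_code); nb <- sum(b == class_code)
  if (na + nb == 0) return(NA_real_)
  d <- 2 * sum(a == class_code & b == class_code) / (na + nb)
  if (scale == "percent") 100 * d else d
}

#' Average symmetric surface distance for one class
#'
#' Boundary pixels are class pixels with at least one non-class pixel in
#' their 4-neighbourhood (the image border counts as non-class). The ASSD is
#' the mean of the two directed average nearest-boundary Euclidean distances,
#' scaled to millimetres by the pixel spacing. Undefined (`NA`) when the
#' class is absent from either mask.
#'
#' @inheritParams dsc
#' @param spacing mm per pixel, length 2 (row, col); taken from the masks
#'   when omitted, and `c(1, 1)` (pixel units) if unavailable there.
#' @return ASSD in mm (or pixels when spacing is 1), `NA` if undefined.
#' @export
assd <- function(a, b, class_code, spacing = NULL) {
  sa <- mask_spacing(a); sb <- mask_spacing(b)
  a <- as_class_grid(a); b <- as_class_grid(b)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  if (is.null(spacing)) {
    spacing <- if (!anyNA(sa)) sa else if (!anyNA(sb)) sb else c(1, 1)
  }
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  ma <- a == class_code; mb <- b == class_code
  if (!any(ma) || !any(mb)) return(NA_real_)
  ba <- which(cpp_boundary4(ma), arr.ind = TRUE)
  bb <- which(cpp_boundary4(mb), arr.ind = TRUE)
  d <- cpp_directed_surface_dist(ba * 1.0, bb * 1.0, as.numeric(spacing))
  mean(d)
}

#' Per-class sensitivity and specificity
#'
#' One-vs-rest confusion counts for the class: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), as percentages. Not symmetric in
#' (truth, prediction). A zero denominator yields `NA` for that component.
#'
#' @param truth,prediction [label_mask()]s or integer grids of equal shape.
#' @param class_code Tissue code to binarize on.
#' @return Named numeric vector `c(sensitivity=, specificity=)` in percent.
#' @export
sensitivity_specificity <- function(truth, prediction, class_code) {
  a <- as_class_grid(truth); b <- as_class_grid(prediction)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  ta <- a == class_code; pb <- b == class_code
  tp <- sum(ta & pb); fn <- sum(ta & !pb)
  tn <- sum(!ta & !pb); fp <- sum(!ta & pb)
  c(sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' All metrics for one image pair
#'
#' @param truth,prediction [label_mask()]s of equal shape.
#' @param classes Class codes to evaluate (default the 7 tissues).
#' @param spacing Optional spacing override for ASSD.
#' @return data.frame with one row per class: `class`, `tissue`, `dsc`,
#'   `assd`, `sensitivity`, `specificity` and undefined-metric flags.
#' @export
seg_metrics <- function(truth, prediction, classes = 1:7, spacing = NULL) {
  rows <- lapply(classes, function(k) {
    ss <- sensitivity_specificity(truth, prediction, k)
    d <- dsc(truth, prediction, k)
    a <- assd(truth, prediction, k, spacing)
    data.frame(class = k, tissue = tissue_names()[k], dsc = d, assd = a,
               sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]],
               dsc_defined = !is.na(d), assd_defined = !is.na(a))
  })
  do.call(rbind, rows)
}

#' k-fold cross-validation plan
#'
#' Splits subjects (never slices) into k folds whose sizes differ by at most
#' one; every subject is held out exactly once. Reproducible by seed.
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param k Number of folds (the protocol used 10).
#' @param seed RNG seed for the assignment.
#' @return Object of class `cv_plan`: data.frame (`subject_id`, `fold`).
#' @export
make_cv_plan <- function(subject_ids, k = 10, seed = NULL) {
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (k < 2 || k > n) stop("k must lie in [2, number of subjects]")
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  structure(data.frame(subject_id = subject_ids, fold = fold),
            class = c("cv_plan", "data.frame"))
}

sample_ids <- function(samples) {
  vapply(samples, function(s) s$meta$subject_id, character(1))
}

# aggregate per-image metric rows into per-fold then overall mean +/- sd
aggregate_report <- function(per_image, k) {
  agg <- function(df, by) {
    out <- stats::aggregate(df[c("dsc", "assd", "sensitivity", "specificity")],
                            by = by, FUN = function(v) mean(v, na.rm = TRUE))
    out
  }
  fold_summary <- agg(per_image,
                      list(fold = per_image$fold, class = per_image$class,
                           tissue = per_image$tissue))
  mean_sd <- function(v) c(mean = mean(v, na.rm = TRUE),
                           sd = stats::sd(v))
  rows <- lapply(split(fold_summary, fold_summary$class), function(df) {
    data.frame(class = df$class[1], tissue = df$tissue[1],
               dsc_mean = mean(df$dsc, na.rm = TRUE),
               dsc_sd = stats::sd(df$dsc),
               assd_mean = mean(df$assd, na.rm = TRUE),
               assd_sd = stats::sd(df$assd),
               sensitivity_mean = mean(df$sensitivity, na.rm = TRUE),
               sensitivity_sd = stats::sd(df$sensitivity),
               specificity_mean = mean(df$specificity, na.rm = TRUE),
               specificity_sd = stats::sd(df$specificity))
  })
  list(fold_summary = fold_summary, summary = do.call(rbind, rows))
}

#' Run k-fold cross-validation
#'
#' Trains one model per fold on the other k-1 folds and evaluates on the
#' held-out subjects; reports per-image metrics, per-fold means and the
#' across-fold mean and standard deviation per class (the reporting
#' convention "average +/- standard deviation of k-fold cross validation").
#' The split is by subject, never by slice.
#'
#' @param samples List of 2-D samples with `meta$subject_id`.
#' @param k Number of folds.
#' @param model_factory `function(train_samples, tc)` returning a prediction
#'   function `function(sample) -> label_mask`. See [unet_model_factory()]
#'   and [oracle_model_factory()].
#' @param tc A [train_config()] forwarded to the factory.
#' @param classes Class codes to score.
#' @param seed Seed for the fold assignment (defaults to `tc$seed`).
#' @return Object of class `seg_metrics_report`: `per_image`, `fold_summary`,
#'   `summary`, `timing` (seconds per slice), `k`, `plan`.
#' @export
run_cv <- function(samples, k = 10, model_factory = oracle_model_factory(),
                   tc = train_config(), classes = 1:7, seed = tc$seed) {
  ids <- sample_ids(samples)
  plan <- make_cv_plan(ids, k, seed)
  per_image <- list()
  timing <- list()
  for (f in seq_len(k)) {
    test_ids <- plan$subject_id[plan$fold == f]
    train_samples <- samples[!ids %in% test_ids]
    test_samples <- samples[ids %in% test_ids]
    predict_fn <- model_factory(train_samples, tc)
    for (s in test_samples) {
      t0 <- proc.time()[["elapsed"]]
      pred <- predict_fn(s)
      dt <- proc.time()[["elapsed"]] - t0
      m <- seg_metrics(s$labels, pred, classes)
      m$fold <- f
      m$subject_id <- s$meta$subject_id
      m$domain <- if (!is.null(s$meta$domain)) s$meta$domain else NA
      per_image[[length(per_image) + 1L]] <- m
      timing[[length(timing) + 1L]] <-
        data.frame(fold = f, subject_id = s$meta$subject_id,
                   seconds_per_slice = dt)
    }
  }
  per_image <- do.call(rbind, per_image)
  agg <- aggregate_report(per_image, k)
  structure(list(per_image = per_image, fold_summary = agg$fold_summary,
                 summary = agg$summary,
                 timing = do.call(rbind, timing), k = k, plan = plan),
            class = "seg_metrics_report")
}

#' @export
print.seg_metrics_report <- function(x, ...) {
  cat(sprintf("<seg_metrics_report> k = %d, %d image evaluations\n",
              x$k, length(unique(x$per_image$subject_id))))
  s <- x$summary
  cat(sprintf("  mean DSC over classes: %.2f%%\n", mean(s$dsc_mean)))
  print(s, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Prediction-function factories for the CV harness
#'
#' `oracle_model_factory` returns the ground-truth labels (an identity
#' pipeline used to validate the harness: it must score DSC 100, sd 0).
#' `unet_model_factory` trains a fresh Dense U-Net per fold.
#' `refseg_model_factory` applies the threshold protocol (no training).
#'
#' @return A `model_factory` suitable for [run_cv()].
#' @export
oracle_model_factory <- function() {
  function(train_samples, tc) function(sample) sample$labels
}

#' @rdname oracle_model_factory
#' @param config A [model_config()].
#' @export
unet_model_factory <- function(config = model_config()) {
  force(config)
  function(train_samples, tc) {
    net <- build_dense_unet(config)
    trained <- train_unet(net, train_samples, tc)
    function(sample) predict(trained, sample$image)$labels
  }
}

#' @rdname oracle_model_factory
#' @param scheme A [threshold_scheme()].
#' @export
refseg_model_factory <- function(scheme = threshold_scheme()) {
  force(scheme)
  function(train_samples, tc) function(sample) refseg(sample$image, scheme)
}

#' Cross-domain robustness evaluation
#'
#' Scores one trained model on samples from both scanner domains and reports
#' per-domain class tables plus per-class DSC deltas (domain A minus domain
#' B), mirroring the test-on-unseen-scanner experiment.
#'
#' @param predict_fn Prediction function `function(sample) -> label_mask`
#'   (e.g. the output of a model factory), or a `trained_unet`.
#' @param samples List of 2-D samples carrying `meta$domain` tags covering
#'   both domains.
#' @param classes Class codes to score.
#' @return Object of class `cross_domain_report`: `per_domain` (named list of
#'   per-class summary tables), `delta` (per-class and mean DSC drop A - B),
#'   `per_image`.
#' @export
cross_domain_eval <- function(predict_fn, samples, classes = 1:7) {
  if (inherits(predict_fn, "trained_unet")) {
    trained <- predict_fn
    predict_fn <- function(sample) predict(trained, sample$image)$labels
  }
  domains <- vapply(samples, function(s) s$meta$domain, character(1))
  if (length(unique(domains)) < 2)
    stop("samples must cover both domains")
  per_image <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    m <- seg_metrics(s$labels, predict_fn(s), classes)
    m$subject_id <- s$meta$subject_id
    m$domain <- domains[i]
    per_image[[i]] <- m
  }
  per_image <- do.call(rbind, per_image)
  per_domain <- lapply(split(per_image, per_image$domain), function(df) {
    out <- stats::aggregate(
      df[c("dsc", "assd", "sensitivity", "specificity")],
      by = list(class = df$class, tissue = df$tissue),
      FUN = function(v) mean(v, na.rm = TRUE))
    out[order(out$class), ]
  })
  dA <- per_domain[["A"]]; dB <- per_domain[["B"]]
  delta <- data.frame(class = dA$class, tissue = dA$tissue,
                      dsc_delta = dA$dsc - dB$dsc)
  structure(list(per_domain = per_domain, delta = delta,
                 mean_dsc = vapply(per_domain, function(d) mean(d$dsc),
                                   numeric(1)),
                 per_image = per_image),
            class = "cross_domain_report")
}

#' @export
print.cross_domain_report <- function(x, ...) {
  cat("<cross_domain_report>\n")
  for (d in names(x$per_domain))
    cat(sprintf("  domain %s: mean DSC %.2f%%\n", d, x$mean_dsc[[d]]))
  cat(sprintf("  mean DSC drop (A - B): %.2f\n",
              x$mean_dsc[["A"]] - x$mean_dsc[["B"]]))
  invisible(x)
}
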