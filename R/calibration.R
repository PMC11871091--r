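#' Fit the HU-to-density calibration line from hydroxyapatite rods
#'
#' Each scan carries hydroxyapatite reference rods of known concentration
#' (protocol values 150, 75 and 0 mg/cm3). The fit is the ordinary
#' least-squares line mapping measured mean rod HU to nominal concentration.
#'
#' @param image A [ct_image()] (2-D slice).
#' @param rod_rois List of logical matrices (same shape as the slice), one
#'   region of interest per rod. Must be non-empty and pairwise disjoint.
#' @param nominal Numeric vector of nominal concentrations (mg/cm3), one per
#'   ROI.
#' @return Object of class `calibration_fit` with elements `slope`
#'   ((mg/cm3)/HU), `intercept` (mg/cm3), `r_squared` and `rod_means`
#'   (data.frame of nominal concentration and measured mean HU).
#' @export
fit_calibration <- function(image, rod_rois, nominal) {
  stopifnot(inherits(image, "ct_image"))
  if (!is.matrix(image$values)) stop("calibration expects a 2-D slice")
  if (length(rod_rois) < 2) stop("need at least 2 calibration rods")
  if (length(rod_rois) != length(nominal))
    stop("one nominal concentration per ROI is required")
  counts <- integer(length(rod_rois))
  means <- numeric(length(rod_rois))
  acc <- matrix(FALSE, nrow(image$values), ncol(image$values))
  for (i in seq_along(rod_rois)) {
    roi <- rod_rois[[i]]
    if (!is.logical(roi) || !identical(dim(roi), dim(image$values)))
      stop("ROI ", i, " must be a logical mask matching the image")
    counts[i] <- sum(roi)
    if (counts[i] == 0) stop("ROI ", i, " is empty")
    if (any(acc & roi)) stop("rod ROIs must be disjoint")
    acc <- acc | roi
    means[i] <- mean(image$values[roi])
  }
  if (max(means) - min(means) < sqrt(.Machine$double.eps))
    stop("degenerate calibration: rod mean HUs are identical")
  fit <- stats::lm(nominal ~ means)
  pred <- stats::fitted(fit)
  sst <- sum((nominal - mean(nominal))^2)
  r2 <- if (sst > 0) 1 - sum((nominal - pred)^2) / sst else 1
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = min(max(r2, 0), 1),
         rod_means = data.frame(nominal = nominal, mean_hu = means,
                                n_pixels = counts)),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> density = %.6g * HU + %.6g  (R^2 = %.4f, %d rods)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$rod_means)))
  invisible(x)
}

#' Apply a calibration fit to an image
#'
#' Affine per-pixel map from HU to equivalent hydroxyapatite density. Note
#' that the threshold protocol operates on raw HU; calibrated density output
#' is provided for quantitative use, not as a segmentation preprocessing step.
#'
#' @param image A [ct_image()].
#' @param fit A `calibration_fit`.
#' @return A `ct_image` whose values are densities in mg/cm3 (origin tag
#'   suffixed with `:density`).
#' @export
apply_calibration <- function(image, fit) {
  stopifnot(inherits(image, "ct_image"), inherits(fit, "calibration_fit"))
  out <- image
  out$values <- fit$slope * image$values + fit$intercept
  out$origin <- paste0(image$origin, ":density")
  out
}
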