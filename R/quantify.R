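# Per-tissue quantification: reference-slice areas, 5-slice volumes, average
# HU (optionally height-adjusted) and marrow composition ratios.

#' Select the reference slice of a stack
#'
#' The protocol takes the slice with the thickest femoral neck on the
#' anatomical left. The proxy implemented here is the per-slice count of bone
#' pixels (cortical + trabecular) within the configured half of the image;
#' under the radiological display convention the patient's left is the image
#' right. Ties break toward the inferior-most slice (the largest index, since
#' slices are stored superior to inferior).
#'
#' @param stack A 3-D [ct_image()] (only used for shape checks; may be NULL).
#' @param masks A 3-D [label_mask()] aligned with the stack.
#' @param side `"left"` (patient-left = image-right half, default) or
#'   `"right"`.
#' @return Integer slice index.
#' @export
select_reference_slice <- function(stack, masks, side = c("left", "right")) {
  side <- match.arg(side)
  cls <- masks$classes
  if (!(is.array(cls) && length(dim(cls)) == 3))
    stop("select_reference_slice expects a 3-D mask stack")
  if (!is.null(stack) && !identical(dim(stack$values), dim(cls)))
    stop("stack and masks shapes differ")
  d <- dim(cls)
  cols <- if (side == "left") seq.int(d[2] %/% 2 + 1L, d[2])
          else seq_len(d[2] %/% 2)
  counts <- vapply(seq_len(d[3]), function(s) {
    sl <- cls[, cols, s]
    sum(sl == 1L | sl == 2L)
  }, numeric(1))
  if (all(counts == 0)) stop("no bone in any slice")
  max(which(counts == max(counts)))   # inferior-most among ties
}

#' Cross-sectional tissue area (cm^2)
#'
#' Pixel count times physical pixel area.
#'
#' @param mask A 2-D [label_mask()] (or 3-D with `slice` given).
#' @param class_code Tissue code.
#' @param slice Slice index when `mask` is 3-D.
#' @return Area in cm^2.
#' @export
tissue_area <- function(mask, class_code, slice = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  if (anyNA(mask$pixel_spacing)) stop("pixel spacing is required for areas")
  cls <- mask$classes
  if (!is.matrix(cls)) {
    if (is.null(slice)) stop("3-D mask: give a slice index")
    cls <- cls[, , slice]
  }
  sum(cls == class_code) * prod(mask$pixel_spacing) / 100  # mm^2 -> cm^2
}

#' Tissue volume over a slice window (cm^3)
#'
#' Sum of per-slice areas times slice thickness, over the 5-slice window
#' centred on the reference slice (two slices above and below) unless another
#' window is given.
#'
#' @param masks A 3-D [label_mask()].
#' @param class_code Tissue code.
#' @param reference Reference slice index; default the central slice.
#' @param window Window half-width in slices (default 2, i.e. 5 slices).
#' @param thickness Slice thickness in mm; defaults to the mask metadata.
#' @return Volume in cm^3.
#' @export
tissue_volume <- function(masks, class_code, reference = NULL, window = 2,
                          thickness = NULL) {
  stopifnot(inherits(masks, "label_mask"))
  cls <- masks$classes
  if (!(is.array(cls) && length(dim(cls)) == 3))
    stop("tissue_volume expects a 3-D mask stack")
  ns <- dim(cls)[3]
  if (is.null(reference)) reference <- (ns + 1L) %/% 2L
  lo <- reference - window; hi <- reference + window
  if (lo < 1 || hi > ns)
    stop("slice window [", lo, ", ", hi, "] exceeds the stack (", ns,
         " slices)")
  if (is.null(thickness)) thickness <- masks$slice_thickness
  if (is.na(thickness)) stop("slice thickness is required for volumes")
  areas <- vapply(lo:hi, function(s) tissue_area(masks, class_code, s),
                  numeric(1))
  sum(areas) * thickness / 10  # cm^2 * mm -> cm^3
}

#' Average HU of a tissue, optionally adjusted for height squared
#'
#' @param image A [ct_image()] (2-D, or 3-D with `slice`).
#' @param mask Aligned [label_mask()].
#' @param class_code Tissue code.
#' @param height_m Body height in metres; when given, `ahu_per_h2` (HU/m^2)
#'   is included.
#' @param slice Slice index for 3-D inputs.
#' @return List with `ahu` (HU) and, if height was given, `ahu_per_h2`.
#' @export
ahu <- function(image, mask, class_code, height_m = NULL, slice = NULL) {
  stopifnot(inherits(image, "ct_image"), inherits(mask, "label_mask"))
  v <- image$values; cls <- mask$classes
  if (!identical(dim(v), dim(cls))) stop("image and mask shapes differ")
  if (!is.matrix(v)) {
    if (is.null(slice)) stop("3-D input: give a slice index")
    v <- v[, , slice]; cls <- cls[, , slice]
  }
  px <- cls == class_code
  if (!any(px)) stop("class ", class_code, " is empty")
  out <- list(ahu = mean(v[px]))
  if (!is.null(height_m)) {
    stopifnot(height_m > 0)
    out$ahu_per_h2 <- out$ahu / height_m^2
  }
  out
}

#' Marrow composition ratios
#'
#' HBM and MAT areas as fractions of total bone marrow (TBM = HBM + MAT).
#' The two fractions sum to 1 whenever TBM is non-empty; both are `NA`
#' (flagged undefined) when the marrow is empty.
#'
#' @param mask A 2-D [label_mask()] (or 3-D with `slice`).
#' @param slice Slice index for 3-D masks.
#' @return Named numeric vector `c(hbm_over_tbm=, mat_over_tbm=)`.
#' @export
marrow_ratios <- function(mask, slice = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  cls <- mask$classes
  if (!is.matrix(cls)) {
    if (is.null(slice)) stop("3-D mask: give a slice index")
    cls <- cls[, , slice]
  }
  hbm <- sum(cls == 3L); mat <- sum(cls == 4L)
  tbm <- hbm + mat
  if (tbm == 0)
    return(c(hbm_over_tbm = NA_real_, mat_over_tbm = NA_real_))
  h <- hbm / tbm
  # complement, so the pair sums to 1 exactly in floating point
  c(hbm_over_tbm = h, mat_over_tbm = 1 - h)
}

#' Quantify one subject
#'
#' Computes the full quantitative report from a stack and its label masks:
#' per-tissue reference-slice area (cm^2) and 5-slice volume (cm^3), average
#' muscle HU with the height-squared adjustment, total bone marrow area and
#' the HBM/TBM and MAT/TBM fractions. For 2-D inputs areas are reported and
#' volumes are `NA`.
#'
#' @param image A [ct_image()] (2-D or 3-D).
#' @param masks Aligned [label_mask()].
#' @param height_m Body height in metres (optional).
#' @param subject_id,domain Metadata copied into the output row.
#' @return One-row data.frame.
#' @export
quantify_subject <- function(image, masks, height_m = NULL,
                             subject_id = NA_character_, domain = NA_character_) {
  stopifnot(inherits(image, "ct_image"), inherits(masks, "label_mask"))
  is3d <- !is.matrix(masks$classes)
  ref <- if (is3d) select_reference_slice(image, masks) else 1L
  sl <- if (is3d) ref else NULL
  tn <- tissue_names()
  areas <- vapply(1:7, function(k) tissue_area(masks, k, sl), numeric(1))
  vols <- if (is3d)
    vapply(1:7, function(k) tissue_volume(masks, k, reference = ref),
           numeric(1))
  else rep(NA_real_, 7)
  amu <- ahu(image, masks, class_code = 5L, height_m = height_m, slice = sl)
  ratios <- marrow_ratios(masks, slice = sl)
  row <- data.frame(subject_id = subject_id, domain = domain,
                    height_m = if (is.null(height_m)) NA_real_ else height_m,
                    reference_slice = ref)
  for (k in 1:7) row[[paste0("area_", tn[k])]] <- areas[k]
  for (k in 1:7) row[[paste0("volume_", tn[k])]] <- vols[k]
  row$ahu_muscle <- amu$ahu
  row$ahu_muscle_per_h2 <-
    if (is.null(height_m)) NA_real_ else amu$ahu_per_h2
  row$tbm_area <- areas[3] + areas[4]
  row$hbm_over_tbm <- ratios[["hbm_over_tbm"]]
  row$mat_over_tbm <- ratios[["mat_over_tbm"]]
  row
}

#' Quantify a cohort
#'
#' One row per subject; by default the samples' own label masks (ground truth
#' or reference segmentation) are used, or supply predicted masks.
#'
#' @param samples List of samples (image, labels, meta).
#' @param masks Optional list of [label_mask()]s overriding `sample$labels`.
#' @return data.frame suitable for export to external statistics tools.
#' @export
quantify_cohort <- function(samples, masks = NULL) {
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    m <- if (is.null(masks)) s$labels else masks[[i]]
    quantify_subject(s$image, m, height_m = s$meta$height_m,
                     subject_id = s$meta$subject_id, domain = s$meta$domain)
  })
  do.call(rbind, rows)
}
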