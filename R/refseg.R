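#' Hounsfield-unit threshold scheme
#'
#' The per-compartment HU intervals of the reference-segmentation protocol.
#' Defaults are the protocol values: cortical bone > 300, cancellous
#' (trabecular) bone 150-300, HBM 50-150, MAT < 50 (both inside the marrow
#' cavity), muscle -30 to 500, and fat (IMAT and SAT alike) < -30. Interval
#' convention is half-open, lower bound inclusive: `[low, high)`; the written
#' ranges touch (150-300 vs > 300), so half-open intervals make the partition
#' exact.
#'
#' @param cortical_min HU at and above which shell pixels are cortical bone.
#' @param trabecular_range `[low, high)` HU interval for trabecular bone.
#' @param hbm_range `[low, high)` HU interval for haematopoietic marrow.
#' @param mat_max Marrow pixels below this HU are marrow adipose tissue.
#' @param muscle_range `[low, high)` HU interval for muscle.
#' @param fat_max Fascia/subcutaneous pixels below this HU are IMAT/SAT.
#' @param air_cutoff HU above which a pixel can belong to the body.
#' @return Object of class `threshold_scheme`.
#' @export
threshold_scheme <- function(cortical_min = 300,
                             trabecular_range = c(150, 300),
                             hbm_range = c(50, 150),
                             mat_max = 50,
                             muscle_range = c(-30, 500),
                             fat_max = -30,
                             air_cutoff = -200) {
  stopifnot(length(trabecular_range) == 2, length(hbm_range) == 2,
            length(muscle_range) == 2)
  if (!(mat_max <= hbm_range[1] && hbm_range[1] < hbm_range[2] &&
        hbm_range[2] <= trabecular_range[1] &&
        trabecular_range[1] < trabecular_range[2] &&
        trabecular_range[2] <= cortical_min))
    stop("marrow/bone intervals must be ordered and non-overlapping")
  if (!(fat_max <= muscle_range[1] && muscle_range[1] < muscle_range[2]))
    stop("fat threshold must not overlap the muscle interval")
  if (air_cutoff >= fat_max)
    stop("air cutoff must lie below the fat threshold")
  structure(
    list(cortical_min = cortical_min, trabecular_range = trabecular_range,
         hbm_range = hbm_range, mat_max = mat_max,
         muscle_range = muscle_range, fat_max = fat_max,
         air_cutoff = air_cutoff),
    class = "threshold_scheme")
}

#' Read/write a threshold scheme as YAML
#' @param path YAML file.
#' @return A [threshold_scheme()] (for `read_scheme`).
#' @export
read_scheme <- function(path) {
  do.call(threshold_scheme, yaml::read_yaml(path))
}

#' @rdname read_scheme
#' @param scheme A [threshold_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  yaml::write_yaml(unclass(scheme), path)
  invisible(path)
}

#' Derive anatomical compartments from a CT slice
#'
#' Automates the compartment delineation step of the reference protocol (the
#' original protocol drew compartments interactively): body is the largest
#' connected component above the air cutoff (calibration rods form separate,
#' smaller components and are thereby excluded); bone is the
#' morphologically-closed, hole-filled high-attenuation shell; marrow is the
#' bone interior below the trabecular threshold; the fascial compartment is
#' the hole-filled envelope of muscle-range attenuation outside bone; the
#' subcutaneous compartment is the remainder of the body.
#'
#' @param image A 2-D [ct_image()].
#' @param scheme A [threshold_scheme()].
#' @param morph_radius Structuring-element radius in pixels; default scales a
#'   2-pixel disk at 128 px with image size.
#' @return List of logical matrices `body`, `bone`, `marrow`, `fascia`,
#'   `subcutaneous` (class `compartment_masks`). `marrow` is a subset of
#'   `bone`; `bone`, `fascia` and `subcutaneous` are pairwise disjoint.
#' @export
derive_compartments <- function(image, scheme = threshold_scheme(),
                                morph_radius = NULL) {
  stopifnot(inherits(image, "ct_image"), inherits(scheme, "threshold_scheme"))
  v <- image$values
  if (!is.matrix(v)) stop("derive_compartments expects a 2-D slice")
  if (is.null(morph_radius))
    morph_radius <- max(1L, as.integer(round(2 * nrow(v) / 128)))

  cand <- v > scheme$air_cutoff
  if (!any(cand)) stop("empty body: no pixels above the air cutoff")
  body <- fill_holes(largest_component(cand, 8))

  bone_raw <- (v >= scheme$trabecular_range[1]) & body
  if (!any(bone_raw)) stop("no bone component found")
  bone <- fill_holes(mclose(largest_component(bone_raw, 8), morph_radius))
  bone <- bone & body
  marrow <- bone & !(v >= scheme$trabecular_range[1])

  fas_raw <- (v >= scheme$muscle_range[1]) & body & !bone
  if (!any(fas_raw)) stop("no muscle compartment found")
  fascia_env <- mclose(fill_holes(largest_component(fas_raw, 8)), morph_radius)
  fascia_env <- fill_holes(fascia_env) & body
  fascia <- fascia_env & !bone
  subcut <- body & !fascia_env & !bone

  structure(list(body = body, bone = bone, marrow = marrow, fascia = fascia,
                 subcutaneous = subcut),
            class = "compartment_masks")
}

#' Classify tissues by thresholding within compartments
#'
#' Applies the HU threshold protocol inside each compartment. Within the bone
#' shell (bone minus marrow): cortical at/above `cortical_min`, trabecular
#' below. Within the marrow cavity: MAT below `mat_max`, HBM in `hbm_range`,
#' and the residual (at/above the trabecular lower bound) is trabecular bone,
#' the protocol's residual-cancellous rule. Within fascia: muscle in
#' `muscle_range`, IMAT below `fat_max`, background above the muscle interval
#' (calcifications are out of scope). Within subcutaneous: SAT below
#' `fat_max`. All other pixels are background.
#'
#' @param image A 2-D [ct_image()].
#' @param compartments A `compartment_masks` (see [derive_compartments()]).
#' @param scheme A [threshold_scheme()].
#' @return A [label_mask()].
#' @export
classify_tissues <- function(image, compartments,
                             scheme = threshold_scheme()) {
  stopifnot(inherits(image, "ct_image"),
            inherits(compartments, "compartment_masks"))
  v <- image$values
  if (!is.matrix(v)) stop("classify_tissues expects a 2-D slice")
  cls <- matrix(0L, nrow(v), ncol(v))

  shell <- compartments$bone & !compartments$marrow
  cls[shell] <- ifelse(v[shell] >= scheme$cortical_min, 1L, 2L)

  mar <- compartments$marrow
  mv <- v[mar]
  mcls <- rep(2L, length(mv))                       # residual -> trabecular
  mcls[mv >= scheme$hbm_range[1] & mv < scheme$hbm_range[2]] <- 3L
  mcls[mv < scheme$mat_max] <- 4L
  cls[mar] <- mcls

  fas <- compartments$fascia
  fv <- v[fas]
  fcls <- rep(0L, length(fv))                       # >= muscle high -> background
  fcls[fv >= scheme$muscle_range[1] & fv < scheme$muscle_range[2]] <- 5L
  fcls[fv < scheme$fat_max] <- 6L
  cls[fas] <- fcls

  sub <- compartments$subcutaneous
  sv <- v[sub]
  scls <- rep(0L, length(sv))
  scls[sv < scheme$fat_max] <- 7L
  cls[sub] <- scls

  label_mask(cls, image$pixel_spacing, image$slice_thickness)
}

#' Reference segmentation of a slice or stack
#'
#' Convenience wrapper: [derive_compartments()] then [classify_tissues()],
#' per slice for 3-D stacks.
#'
#' @inheritParams derive_compartments
#' @return A [label_mask()] matching the image shape.
#' @export
refseg <- function(image, scheme = threshold_scheme(), morph_radius = NULL) {
  stopifnot(inherits(image, "ct_image"))
  if (is.matrix(image$values)) {
    comp <- derive_compartments(image, scheme, morph_radius)
    return(classify_tissues(image, comp, scheme))
  }
  d <- dim(image$values)
  out <- array(0L, d)
  for (s in seq_len(d[3])) {
    sl <- get_slice(image, s)
    comp <- derive_compartments(sl, scheme, morph_radius)
    out[, , s] <- classify_tissues(sl, comp, scheme)$classes
  }
  label_mask(out, image$pixel_spacing, image$slice_thickness)
}
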